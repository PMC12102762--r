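# NAMD-style "fepout" parsing and writing, plus a generic engine-agnostic
# TSV work table.  A fepout file holds, per lambda window:
#
#   #NEW FEP WINDOW: LAMBDA SET TO <l1> LAMBDA2 <l2>
#   FepEnergy:  <step> <elec0> <elec1> <vdw0> <vdw1> <dE> <dE_avg> <T> <dG>
#   ...
#   #STARTING COLLECTION OF ENSEMBLE AVERAGE      (optional; earlier
#                                                  FepEnergy lines are
#                                                  equilibration, discarded)
#   FepEnergy:  ...
#   #Free energy change for lambda window [ <l1> <l2> ] is <dG> ...

#' Parse a NAMD-style fepout file into a work table
#'
#' Equilibration samples (FepEnergy records before the
#' "#STARTING COLLECTION OF ENSEMBLE AVERAGE" marker of a window) are
#' discarded.  Window direction is inferred from the lambda ordering.
#'
#' @param path Path to a fepout text file.
#' @return A tibble with one row per retained sample: `lambda_start`,
#'   `lambda_end`, `direction`, `step`, `delta_u` (kcal/mol),
#'   `temperature` (K, `NA` when the file carries none).
#' @export
parse_fepout <- function(path) {
  if (!file.exists(path)) abort(sprintf("cannot read fepout: '%s' does not exist", path))
  lines <- readLines(path, warn = FALSE)
  win_start <- grep("^#NEW FEP WINDOW:", lines)
  if (!length(win_start)) abort(sprintf("'%s' contains no FEP window headers", path))
  win_end <- c(win_start[-1] - 1L, length(lines))
  out <- vector("list", length(win_start))
  for (w in seq_along(win_start)) {
    header <- lines[win_start[w]]
    m <- regmatches(header,
                    regexec("LAMBDA SET TO ([0-9.eE+-]+) LAMBDA2 ([0-9.eE+-]+)", header))[[1]]
    if (length(m) != 3) {
      abort(sprintf("malformed FEP window header at line %d of '%s'", win_start[w], path))
    }
    l1 <- as.numeric(m[2]); l2 <- as.numeric(m[3])
    block <- win_start[w]:win_end[w]
    collect_at <- grep("^#STARTING COLLECTION", lines[block])
    data_lines <- block[grepl("^FepEnergy:", lines[block])]
    if (length(collect_at)) {
      data_lines <- data_lines[data_lines > block[collect_at[1]]]
    }
    if (!length(data_lines)) {
      abort(sprintf("window %g -> %g (line %d of '%s') has no samples",
                    l1, l2, win_start[w], path))
    }
    fields <- strsplit(trimws(sub("^FepEnergy:", "", lines[data_lines])), "\\s+")
    nums <- lapply(fields, function(x) suppressWarnings(as.numeric(x)))
    bad <- which(vapply(nums, function(x) length(x) < 6 || anyNA(x[1:6]), logical(1)))
    if (length(bad)) {
      abort(sprintf("malformed FepEnergy record at line %d of '%s'",
                    data_lines[bad[1]], path))
    }
    out[[w]] <- tibble(
      lambda_start = l1,
      lambda_end = l2,
      direction = if (l2 >= l1) "forward" else "backward",
      step = vapply(nums, function(x) x[1], numeric(1)),
      delta_u = vapply(nums, function(x) x[6], numeric(1)),
      temperature = vapply(nums, function(x) if (length(x) >= 8) x[8] else NA_real_,
                           numeric(1))
    )
  }
  bind_rows(out)
}

#' Write a work table as a fepout-dialect text file
#'
#' @param work A work table (`lambda_start`, `lambda_end`, `delta_u`, and
#'   optionally `direction`, `step`, `temperature`).
#' @param path Output path.
#' @param equil_samples Optional per-window equilibration samples to emit
#'   before the collection marker (discarded on re-parse); default 0.
#' @return `path`, invisibly.
#' @export
write_fepout <- function(work, path, equil_samples = 0) {
  work <- normalise_work(work)
  if (!"temperature" %in% names(work)) work$temperature <- NA_real_
  con <- file(path, "w")
  on.exit(close(con))
  keys <- work |> distinct(.data$lambda_start, .data$lambda_end, .data$direction)
  for (i in seq_len(nrow(keys))) {
    sub <- work |> filter(.data$lambda_start == keys$lambda_start[i],
                          .data$lambda_end == keys$lambda_end[i],
                          .data$direction == keys$direction[i])
    writeLines(sprintf("#NEW FEP WINDOW: LAMBDA SET TO %g LAMBDA2 %g",
                       keys$lambda_start[i], keys$lambda_end[i]), con)
    if (equil_samples > 0) {
      for (e in seq_len(equil_samples)) {
        writeLines(sprintf("FepEnergy: %10d %12.4f %12.4f %12.4f %12.4f %12.6f %12.6f %10.4f %12.6f",
                           e, 0, 0, 0, 0, sub$delta_u[1], sub$delta_u[1],
                           sub$temperature[1] %|NA|% 0, 0), con)
      }
    }
    writeLines("#STARTING COLLECTION OF ENSEMBLE AVERAGE", con)
    steps <- if ("step" %in% names(sub)) sub$step else seq_len(nrow(sub))
    writeLines(sprintf("FepEnergy: %10d %12.4f %12.4f %12.4f %12.4f %12.6f %12.6f %10.4f %12.6f",
                       steps, 0, 0, 0, 0, sub$delta_u,
                       cumsum(sub$delta_u) / seq_len(nrow(sub)),
                       ifelse(is.na(sub$temperature), 0, sub$temperature), 0), con)
    writeLines(sprintf("#Free energy change for lambda window [ %g %g ] is 0 ; net change until now is 0",
                       keys$lambda_start[i], keys$lambda_end[i]), con)
  }
  invisible(path)
}

`%|NA|%` <- function(x, y) if (is.na(x)) y else x

#' Read a generic TSV work table
#'
#' Engine-agnostic alternative to fepout: a tab-separated file with a header
#' row and columns `lambda_start`, `lambda_end`, `direction`, `delta_u`
#' (and optionally `temperature`).  Lines starting with '#' are comments.
#'
#' @param path Path to the TSV file.
#' @return A work-table tibble.
#' @export
read_work_table <- function(path) {
  tbl <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  normalise_work(tbl)
}

#' Write a work table as TSV
#'
#' @param work A work-table tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_work_table <- function(work, path) {
  readr::write_tsv(normalise_work(work), path, progress = FALSE)
  invisible(path)
}
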