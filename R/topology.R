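# Structure/topology model: atom tables, PDB I/O (via bio3d), selections and
# the chain-concatenated residue index used for plotting multi-chain profiles.

# Residue names treated as membrane lipids.  Covers the pseudo-lipids written
# by the synthetic generator plus common CHARMM lipid names.
LIPID_RESNAMES <- c(
  "PC", "PE", "PI", "PS", "SM", "PA", "CHL",
  "POPC", "POPE", "POPS", "POPI", "POPA", "DPPC", "DOPC", "DOPE", "DOPS",
  "PSM", "SAPI", "CHL1", "CHOL"
)

SOLVENT_RESNAMES <- c("TIP3", "TIP", "HOH", "WAT", "SPC", "SOD", "CLA", "POT",
                      "CAL", "MG", "NA", "CL", "K")

infer_element <- function(atom_name, element = NULL) {
  nm <- toupper(trimws(atom_name))
  el <- if (is.null(element)) rep(NA_character_, length(nm)) else toupper(trimws(element))
  el[!is.na(el) & el == ""] <- NA_character_
  missing <- is.na(el)
  if (any(missing)) {
    # CHARMM PDB dialects often omit the element column; fall back to the
    # leading-letter rule after stripping digits (H, 1H, 2HB1, ...).
    stripped <- sub("^[0-9]+", "", nm[missing])
    el[missing] <- substr(stripped, 1, 1)
  }
  el
}

classify_segment <- function(residue_name) {
  rn <- toupper(trimws(residue_name))
  dplyr::case_when(
    rn %in% LIPID_RESNAMES ~ "membrane",
    rn %in% SOLVENT_RESNAMES ~ "solvent",
    TRUE ~ "protein"
  )
}

new_topology <- function(atoms) {
  atoms <- as_tibble(atoms)
  required <- c("atom_index", "atom_name", "element", "residue_id",
                "residue_name", "chain", "segment", "is_heavy")
  missing <- setdiff(required, names(atoms))
  if (length(missing)) {
    abort(paste0("topology is missing columns: ", paste(missing, collapse = ", ")))
  }
  class(atoms) <- c("pp_topology", class(atoms))
  atoms
}

#' Build a topology table from atom records
#'
#' Constructs the atom table all analyses consume.  Elements are inferred from
#' atom names when not supplied, heavy-atom status is derived from the
#' element, and each atom is classified into a `segment`
#' (`"protein"`, `"membrane"` or `"solvent"`) from its residue name.
#'
#' @param atom_name Character vector of atom names.
#' @param residue_id Integer vector of source residue numbers (1-based).
#' @param residue_name Character vector of residue names.
#' @param chain Character vector of chain identifiers.
#' @param element Optional character vector of element symbols; inferred from
#'   `atom_name` where missing.
#'
#' @return A tibble of class `pp_topology` with columns `atom_index` (1-based),
#'   `atom_name`, `element`, `residue_id`, `residue_name`, `chain`, `segment`
#'   and `is_heavy`.
#' @export
topology <- function(atom_name, residue_id, residue_name, chain,
                     element = NULL) {
  n <- length(atom_name)
  residue_id <- rep_len(residue_id, n)
  residue_name <- rep_len(residue_name, n)
  chain <- rep_len(chain, n)
  el <- infer_element(atom_name, element)
  new_topology(tibble(
    atom_index = seq_len(n),
    atom_name = as.character(atom_name),
    element = el,
    residue_id = as.integer(residue_id),
    residue_name = as.character(residue_name),
    chain = as.character(chain),
    segment = classify_segment(residue_name),
    is_heavy = el != "H"
  ))
}

new_frame <- function(coords, box = c(NA_real_, NA_real_, NA_real_), time = 0) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 3)
  structure(list(coords = coords, box = as.numeric(box), time = time),
            class = "pp_frame")
}

#' Read a PDB structure into a topology and a coordinate frame
#'
#' Parses a PDB file (via bio3d) into the package's atom table plus a single
#' coordinate frame in Angstrom.  The box is taken from the CRYST1 record when
#' present.
#'
#' @param path Path to a readable PDB file.
#' @return A list with elements `topology` (a [topology()] tibble) and
#'   `frame` (coordinates matrix `n x 3` in Angstrom, `box` lengths, `time`).
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) abort(sprintf("cannot read structure: '%s' does not exist", path))
  lines <- readLines(path, warn = FALSE)
  atom_lines <- grep("^(ATOM  |HETATM)", lines)
  if (!length(atom_lines)) abort(sprintf("no atoms found in '%s'", path))
  # Pre-scan coordinates so malformed records are reported with a line number
  # (bio3d silently NA-fills them).
  for (i in atom_lines) {
    xyz <- suppressWarnings(as.numeric(c(substr(lines[i], 31, 38),
                                         substr(lines[i], 39, 46),
                                         substr(lines[i], 47, 54))))
    if (anyNA(xyz)) {
      abort(sprintf("malformed ATOM record at line %d of '%s'", i, path))
    }
  }
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  chain <- ifelse(is.na(at$chain), "A", at$chain)
  top <- topology(
    atom_name = at$elety,
    residue_id = at$resno,
    residue_name = at$resid,
    chain = chain,
    element = if ("elesy" %in% names(at)) at$elesy else NULL
  )
  box <- c(NA_real_, NA_real_, NA_real_)
  cr <- grep("^CRYST1", lines, value = TRUE)
  if (length(cr)) {
    box <- suppressWarnings(as.numeric(c(substr(cr[1], 7, 15),
                                         substr(cr[1], 16, 24),
                                         substr(cr[1], 25, 33))))
  }
  list(topology = top,
       frame = new_frame(cbind(at$x, at$y, at$z), box = box, time = 0))
}

#' Write a topology and frame to a PDB file
#'
#' @param topology A [topology()] tibble.
#' @param frame A frame as returned by [read_structure()] (list with `coords`
#'   and optional `box`), or an `n x 3` coordinate matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(topology, frame, path) {
  coords <- if (is.list(frame)) frame$coords else frame
  stopifnot(nrow(coords) == nrow(topology))
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(coords)),
    resno = topology$residue_id,
    resid = topology$residue_name,
    eleno = topology$atom_index,
    elety = topology$atom_name,
    chain = topology$chain,
    elesy = topology$element
  )
  box <- if (is.list(frame)) frame$box else NULL
  if (!is.null(box) && all(is.finite(box))) {
    cryst <- sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                     box[1], box[2], box[3], 90, 90, 90)
    lines <- readLines(path, warn = FALSE)
    writeLines(c(cryst, lines), path)
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# Selection mini-grammar:
#   expr    := term ("or" term)*
#   term    := factor ("and" factor)*
#   factor  := "not" factor | "(" expr ")" | primary
#   primary := protein | membrane | solvent | heavy | all
#            | chain <id>... | resid <n|a:b>... | name <atom>...

tokenize_selection <- function(expression) {
  expression <- gsub("([()])", " \\1 ", expression)
  toks <- strsplit(trimws(expression), "\\s+")[[1]]
  toks[toks != ""]
}

parse_selection <- function(tokens, topology) {
  pos <- 1L
  peek <- function() if (pos <= length(tokens)) tokens[pos] else NA_character_
  advance <- function() {
    t <- peek(); pos <<- pos + 1L; t
  }
  fail <- function(msg) abort(sprintf("selection syntax error: %s", msg))

  keyword <- c("and", "or", "not", "(", ")", "protein", "membrane", "solvent",
               "heavy", "all", "chain", "resid", "name")

  parse_expr <- function() {
    v <- parse_term()
    while (!is.na(peek()) && tolower(peek()) == "or") {
      advance()
      v <- v | parse_term()
    }
    v
  }
  parse_term <- function() {
    v <- parse_factor()
    while (!is.na(peek()) && tolower(peek()) == "and") {
      advance()
      v <- v & parse_factor()
    }
    v
  }
  parse_factor <- function() {
    t <- peek()
    if (is.na(t)) fail("unexpected end of expression")
    if (tolower(t) == "not") {
      advance()
      return(!parse_factor())
    }
    if (t == "(") {
      advance()
      v <- parse_expr()
      if (is.na(peek()) || peek() != ")") fail("missing closing parenthesis")
      advance()
      return(v)
    }
    parse_primary()
  }
  take_args <- function() {
    args <- character()
    while (!is.na(peek()) && !(tolower(peek()) %in% keyword)) {
      args <- c(args, advance())
    }
    args
  }
  parse_primary <- function() {
    t <- tolower(advance())
    switch(t,
      protein = topology$segment == "protein",
      membrane = topology$segment == "membrane",
      solvent = topology$segment == "solvent",
      heavy = topology$is_heavy,
      all = rep(TRUE, nrow(topology)),
      chain = {
        args <- take_args()
        if (!length(args)) fail("'chain' needs at least one identifier")
        topology$chain %in% args
      },
      name = {
        args <- take_args()
        if (!length(args)) fail("'name' needs at least one atom name")
        toupper(topology$atom_name) %in% toupper(args)
      },
      resid = {
        args <- take_args()
        if (!length(args)) fail("'resid' needs at least one id or range a:b")
        keep <- rep(FALSE, nrow(topology))
        for (a in args) {
          if (grepl("^-?[0-9]+:-?[0-9]+$", a)) {
            rng <- as.integer(strsplit(a, ":")[[1]])
            keep <- keep | (topology$residue_id >= min(rng) &
                              topology$residue_id <= max(rng))
          } else if (grepl("^-?[0-9]+$", a)) {
            keep <- keep | topology$residue_id == as.integer(a)
          } else {
            fail(sprintf("bad resid token '%s'", a))
          }
        }
        keep
      },
      fail(sprintf("unknown token '%s'", t))
    )
  }

  mask <- parse_expr()
  if (pos <= length(tokens)) {
    fail(sprintf("unexpected trailing token '%s'", tokens[pos]))
  }
  mask
}

#' Select atoms with a small selection grammar
#'
#' Supported syntax: the keywords `protein`, `membrane`, `solvent`, `heavy`,
#' `all`; `chain A B`; `resid 10 12:20`; `name CA CB`; combined with `and`,
#' `or`, `not` and parentheses.
#'
#' @param topology A [topology()] tibble.
#' @param expression Selection expression string.
#' @return An integer vector of 1-based atom indices (class `pp_selection`)
#'   carrying the expression as attribute `expression`.  An empty result
#'   raises a warning, not an error.
#' @export
make_selection <- function(topology, expression) {
  stopifnot(is.character(expression), length(expression) == 1L)
  mask <- parse_selection(tokenize_selection(expression), topology)
  idx <- which(mask)
  if (!length(idx)) {
    warn(sprintf("selection '%s' matched no atoms", expression))
  }
  structure(as.integer(idx), expression = expression, class = "pp_selection")
}

# ---------------------------------------------------------------------------
# Global residue index: the first chain keeps its source numbering; each
# subsequent chain is appended after the previous chain's maximum, so a
# two-chain protein (1-333, then 76-293) plots as 1-551.

#' Chain-concatenated residue index map
#'
#' The first chain keeps its source residue numbering as the global index;
#' every subsequent chain is appended after the previous chain's maximum
#' index, preserving its internal offsets.
#'
#' @param topology A [topology()] tibble (only `segment == "protein"` residues
#'   are mapped by default).
#' @param segments Segments to include (default `"protein"`).
#' @return A tibble with columns `chain`, `residue_id`, `residue_name`,
#'   `global_index`; one row per residue, bijective.
#' @export
residue_index_map <- function(topology, segments = "protein") {
  res <- topology |>
    filter(.data$segment %in% segments) |>
    distinct(.data$chain, .data$residue_id, .data$residue_name)
  chains <- unique(res$chain)
  offset <- 0L
  out <- vector("list", length(chains))
  for (k in seq_along(chains)) {
    rc <- res |> filter(.data$chain == chains[k]) |> arrange(.data$residue_id)
    if (k == 1L) {
      rc$global_index <- rc$residue_id
    } else {
      rc$global_index <- offset + (rc$residue_id - min(rc$residue_id) + 1L)
    }
    offset <- max(rc$global_index)
    out[[k]] <- rc
  }
  bind_rows(out)
}

#' Look up the global plot index of one residue
#'
#' @param map A [residue_index_map()] tibble.
#' @param chain,residue_id Residue identity in source numbering.
#' @return The integer global index.
#' @export
map_residue_index <- function(map, chain, residue_id) {
  hit <- map$global_index[map$chain == chain & map$residue_id == residue_id]
  if (length(hit) != 1L) {
    abort(sprintf("residue %s:%s not found in index map", chain, residue_id))
  }
  hit
}

#' Invert a residue index map
#'
#' @param map A [residue_index_map()] tibble.
#' @param global_index Integer global index.
#' @return A one-row tibble with `chain` and `residue_id`.
#' @export
unmap_residue_index <- function(map, global_index) {
  hit <- map[map$global_index == global_index, c("chain", "residue_id")]
  if (nrow(hit) != 1L) {
    abort(sprintf("global index %s not found in index map", global_index))
  }
  hit
}
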