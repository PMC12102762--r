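# Shared fixtures, built in code at test time.

# A hand-sized two-chain system: chain A protein residues over a tiny
# membrane patch (chain M pseudo-lipids).
tiny_system <- function(n_res = 3, n_lipids = 4, protein_z = 20) {
  prot <- tibble::tibble(
    atom_name = rep(c("CA", "CB", "HA"), n_res),
    residue_id = rep(seq_len(n_res), each = 3),
    residue_name = "ALA",
    chain = "A",
    element = rep(c("C", "C", "H"), n_res)
  )
  lip <- tibble::tibble(
    atom_name = rep(c("P", "C1"), n_lipids),
    residue_id = rep(n_res + seq_len(n_lipids), each = 2),
    residue_name = "PC",
    chain = "M",
    element = rep(c("P", "C"), n_lipids)
  )
  at <- dplyr::bind_rows(prot, lip)
  top <- topology(at$atom_name, at$residue_id, at$residue_name, at$chain,
                  element = at$element)
  set.seed(99)
  coords <- matrix(0, nrow(top), 3)
  pidx <- which(top$chain == "A")
  coords[pidx, ] <- cbind(runif(length(pidx), -5, 5),
                          runif(length(pidx), -5, 5),
                          protein_z + runif(length(pidx), -2, 2))
  midx <- which(top$chain == "M")
  coords[midx, ] <- cbind(runif(length(midx), -8, 8),
                          runif(length(midx), -8, 8),
                          rep(c(16, 14), n_lipids))
  list(topology = top, coords = coords, box = c(60, 60, 120))
}

# Independent brute-force contact oracle: explicit double loop over the
# logistic kernel, z minimum image applied.
brute_contacts <- function(coords, idx_a, idx_b, box_z = NA,
                           steepness = 5, midpoint = 4) {
  total <- 0
  for (i in idx_a) {
    for (j in idx_b) {
      d <- coords[i, ] - coords[j, ]
      if (is.finite(box_z)) d[3] <- d[3] - box_z * round(d[3] / box_z)
      dist <- sqrt(sum(d^2))
      total <- total + 1 / (1 + exp(steepness * (dist - midpoint)))
    }
  }
  total
}

# Independent brute-force depth oracle: scan a residue's heavy atoms for the
# one nearest the centre along z, return its signed offset.
brute_depth <- function(coords, atom_idx, center_z) {
  best <- Inf; out <- NA
  for (i in atom_idx) {
    dz <- coords[i, 3] - center_z
    if (abs(dz) < abs(best)) { best <- dz; out <- dz }
  }
  out
}

# Gaussian Crooks-consistent work pair for one window.
crooks_pair <- function(n, dg, sigma, kT) {
  shift <- sigma^2 / (2 * kT)
  list(forward = rnorm(n, dg + shift, sigma),
       backward = rnorm(n, -dg + shift, sigma))
}

make_pdb_lines <- function(records) {
  # records: list of c(name, resname, chain, resid, x, y, z, element)
  vapply(records, function(r) {
    sprintf("ATOM  %5d %-4s%-4s%1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            1L, r[[1]], r[[2]], r[[3]], as.integer(r[[4]]),
            as.numeric(r[[5]]), as.numeric(r[[6]]), as.numeric(r[[7]]),
            r[[8]])
  }, character(1))
}
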