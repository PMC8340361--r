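# Small in-code fixtures shared across the suite.

toy_windows <- function() {
  site_windows(c(3, 6), c(9, 11), c(14, 17))
}

# Build a PTM record tibble with sensible defaults.
make_ptms <- function(protein = "TOY", species = "H. sapiens",
                      residue_letter = "K", residue_number = 5L,
                      ptm_type = "acetylation", flank = NA_character_,
                      study_count = 1L, position = NULL) {
  n <- max(lengths(list(protein, species, residue_letter, residue_number,
                        ptm_type, study_count)))
  out <- tibble::tibble(
    protein = rep_len(protein, n),
    species = rep_len(species, n),
    residue_letter = rep_len(residue_letter, n),
    residue_number = as.integer(rep_len(residue_number, n)),
    ptm_type = rep_len(ptm_type, n),
    flank = rep_len(flank, n),
    study_count = as.integer(rep_len(study_count, n))
  )
  if (!is.null(position)) out$position <- as.integer(rep_len(position, n))
  out
}

# Independent brute-force LSI oracle: evaluate 10 - n1 - 2*n2 under both
# class assignments and apply the majority rule.
lsi_oracle <- function(ligands) {
  if (length(ligands) == 0) return(0L)
  mono <- c("3", "4", "5")
  m <- sum(ligands %in% mono)
  p <- length(ligands) - m
  lsi_as <- function(n_in, n_out) 10L - (n_in - 1L) - 2L * n_out
  if (m > p) lsi_as(m, p)
  else if (p > m) lsi_as(p, m)
  else {
    both <- c(lsi_as(m, p), lsi_as(p, m))
    stopifnot(both[1] == both[2])
    both[1]
  }
}

all_pip_subsets <- function() {
  codes <- c("3", "4", "5", "34", "35", "45", "345")
  unlist(lapply(0:7, function(k) {
    if (k == 0) list(character(0)) else
      apply(utils::combn(codes, k), 2, identity, simplify = FALSE)
  }), recursive = FALSE)
}
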