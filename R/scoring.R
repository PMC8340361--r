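#' Phosphoinositide class of a ligand code
#'
#' The seven phosphoinositides split into two classes by the number of
#' phosphates on the inositol ring: the monophosphorylated species PI3P,
#' PI4P, PI5P (codes "3", "4", "5") versus the bis/tris species (codes
#' "34", "35", "45", "345").
#'
#' @param code Character vector of ligand codes.
#' @return Character vector, `"mono"` or `"poly"`.
#' @examples
#' pip_class(c("3", "345"))
#' @export
pip_class <- function(code) {
  bad <- setdiff(unique(code), PIP_CODES)
  if (length(bad) > 0) {
    abort(paste0("unknown ligand code(s): ", paste(bad, collapse = ", ")))
  }
  ifelse(code %in% c("3", "4", "5"), "mono", "poly")
}

#' Lipid Specificity Index of a ligand set
#'
#' A domain binding a single phosphoinositide scores the maximum LSI of 10; a
#' domain binding none scores 0. Otherwise the domain is assigned to the
#' phosphoinositide class (mono vs poly, see [pip_class()]) holding the
#' majority of its ligands, and the LSI is 10 minus 1 per *additional*
#' in-class ligand (`n1`) minus 2 per out-of-class ligand (`n2`):
#' `lsi = 10 - n1 - 2*n2`. When the two classes tie the LSI is identical
#' under either choice (the penalty totals coincide exactly when the counts
#' are equal), and `assigned_class` is reported as `"tie"`.
#'
#' @param ligands Character vector of ligand codes (may be empty).
#' @return One-row tibble: `lsi`, `n1`, `n2`, `assigned_class`
#'   (one of "mono", "poly", "tie", "none").
#' @examples
#' compute_lsi(c("3", "34", "35", "45", "345"))  # lsi 5
#' compute_lsi(character(0))                     # non-binder, lsi 0
#' @export
compute_lsi <- function(ligands) {
  if (length(ligands) == 1 && is.na(ligands)) {
    abort("ligand set is undetermined (NA); cannot compute LSI")
  }
  if (anyDuplicated(ligands)) abort("duplicated ligand code")
  if (length(ligands) == 0) {
    return(tibble(lsi = 0L, n1 = 0L, n2 = 0L, assigned_class = "none"))
  }
  cls <- pip_class(ligands)
  n_mono <- sum(cls == "mono")
  n_poly <- sum(cls == "poly")
  if (n_mono > n_poly) {
    assigned <- "mono"; n_in <- n_mono; n_out <- n_poly
  } else if (n_poly > n_mono) {
    assigned <- "poly"; n_in <- n_poly; n_out <- n_mono
  } else {
    # tie: lsi = 10 - (m-1) - 2m = 10 - (m-1) - 2m under either class
    assigned <- "tie"; n_in <- n_mono; n_out <- n_poly
  }
  n1 <- n_in - 1L
  n2 <- n_out
  lsi <- 10L - n1 - 2L * n2
  tibble(lsi = as.integer(lsi), n1 = as.integer(n1), n2 = as.integer(n2),
         assigned_class = assigned)
}

#' Add recomputed LSI columns to a domain table
#'
#' Convenience verb: applies [compute_lsi()] to every ligand-determined row
#' of a domain feature table.
#'
#' @param domains A domain feature tibble with a `ligands` list-column.
#' @return The input with added columns `lsi_recomputed`, `n1`, `n2`,
#'   `assigned_class` (`NA` where the ligand set is undetermined).
#' @export
add_lsi <- function(domains) {
  res <- map(domains$ligands, function(l) {
    if (length(l) == 1 && is.na(l)) {
      tibble(lsi = NA_integer_, n1 = NA_integer_, n2 = NA_integer_,
             assigned_class = NA_character_)
    } else {
      compute_lsi(l)
    }
  })
  res <- bind_rows(res)
  domains$lsi_recomputed <- res$lsi
  domains$n1 <- res$n1
  domains$n2 <- res$n2
  domains$assigned_class <- res$assigned_class
  domains
}

#' Membrane-selectivity class from an LSI value
#'
#' Bins the 0-10 Lipid Specificity Index: 10 is absolute selectivity, 8-9
#' high, 5-7 medium, 1-4 low, and 0 a non-binder ("none").
#'
#' @param lsi Integer vector in 0..10.
#' @return Factor with levels absolute, high, medium, low, none.
#' @examples
#' selectivity_class(c(10, 9, 5, 1, 0))
#' @export
selectivity_class <- function(lsi) {
  if (any(!is.na(lsi) & (lsi < 0 | lsi > 10))) {
    abort("LSI values must lie in 0..10")
  }
  lab <- dplyr::case_when(
    is.na(lsi) ~ NA_character_,
    lsi == 10 ~ "absolute",
    lsi >= 8 ~ "high",
    lsi >= 5 ~ "medium",
    lsi >= 1 ~ "low",
    TRUE ~ "none"
  )
  factor(lab, levels = c("absolute", "high", "medium", "low", "none"))
}

#' Evidence weight of a modification
#'
#' Each modification contributes to a stop score according to how many unique
#' studies report it: a single study adds 1, 2-4 studies add 2, and 5 or more
#' add 3.
#'
#' @param study_count Positive integer vector.
#' @return Integer vector of weights in 1..3.
#' @examples
#' stop_weight(c(1, 4, 5))
#' @export
stop_weight <- function(study_count) {
  if (any(is.na(study_count)) || any(study_count < 1)) {
    abort("study_count must be a positive integer")
  }
  ifelse(study_count >= 5, 3L, ifelse(study_count >= 2, 2L, 1L))
}

#' MET-stop or PIP-stop score of a domain
#'
#' Aggregates modification records (see [aggregate_ptms()]), keeps those of
#' the requested chemistry -- `mode = "met"` selects metabolite modifications
#' of Lys/Arg, `mode = "pip"` selects phosphorylation of Ser/Thr/Tyr -- maps
#' each onto the aligned domain sequence, and sums [stop_weight()] over the
#' modifications whose residue falls inside one of the three consensus
#' membrane-binding site windows. Modifications outside the sites contribute
#' nothing. Records from all species count by default, matching the
#' convention that homolog evidence contributes to a domain's score; set
#' `species` to restrict.
#'
#' @param ptms PTM record tibble (one domain's records; see
#'   [load_ptm_table()]).
#' @param aligned_seq The domain's aligned sequence (possibly gapped).
#' @param windows Site windows (see [site_windows()]).
#' @param mode `"met"` or `"pip"`.
#' @param numbering_offset Integer: source residue number minus ungapped
#'   sequence position (0 when the sequence is numbered from 1).
#' @param species Optional character vector restricting which species'
#'   records count.
#' @return A list with `total` (integer) and `contributions`, a tibble with
#'   one row per counted modification (`protein`, `species`,
#'   `residue_number`, `ptm_type`, `site`, `study_count`, `weight`).
#' @export
compute_stop_score <- function(ptms, aligned_seq, windows,
                               mode = c("met", "pip"),
                               numbering_offset = 0L, species = NULL) {
  mode <- match.arg(mode)
  types <- if (mode == "met") MET_PTM_TYPES else PHOSPHO_PTM_TYPES
  letters_ok <- if (mode == "met") c("K", "R") else c("S", "T", "Y")
  keep <- ptms$ptm_type %in% types & ptms$residue_letter %in% letters_ok
  if (!is.null(species)) keep <- keep & ptms$species %in% species
  sub <- ptms[keep, , drop = FALSE]
  if (nrow(sub) == 0) {
    return(list(total = 0L,
                contributions = tibble(protein = character(), species = character(),
                                       residue_number = integer(),
                                       ptm_type = character(), site = character(),
                                       study_count = integer(), weight = integer())))
  }
  agg <- aggregate_ptms(sub)
  pos <- agg$residue_number - numbering_offset
  n_res <- nchar(gsub("-", "", aligned_seq, fixed = TRUE))
  if (any(pos < 1 | pos > n_res)) {
    bad <- agg[pos < 1 | pos > n_res, ]
    abort(paste0("modification(s) fall outside the sequence: ",
                 paste(paste0(bad$protein, " ", bad$residue_letter,
                              bad$residue_number), collapse = ", ")))
  }
  site <- residue_site(aligned_seq, pos, windows)
  inside <- site != "outside"
  contributions <- tibble(
    protein = agg$protein[inside],
    species = agg$species[inside],
    residue_number = agg$residue_number[inside],
    ptm_type = agg$ptm_type[inside],
    site = as.character(site[inside]),
    study_count = agg$study_count[inside],
    weight = stop_weight(agg$study_count[inside])
  )
  list(total = as.integer(sum(contributions$weight)), contributions = contributions)
}

#' Membrane Affinity Index classification
#'
#' Classifies a domain's bilayer binding as strong (S), weak (W) or none (N).
#' Evidence may be a category -- `"nanomolar"`, `"micromolar"`, `"none"` --
#' or a numeric dissociation constant in micromolar units, cut at 1 uM
#' between S and W.
#'
#' @param evidence Character categories or numeric Kd values (uM).
#' @return Character vector of "S", "W", "N".
#' @examples
#' classify_mai(c("nanomolar", "none"))
#' classify_mai(5)      # Kd = 5 uM -> "W"
#' classify_mai(0.02)   # 20 nM -> "S"
#' @export
classify_mai <- function(evidence) {
  if (is.numeric(evidence)) {
    if (any(evidence < 0, na.rm = TRUE)) abort("Kd cannot be negative")
    return(ifelse(evidence < 1, "S", "W"))
  }
  ok <- evidence %in% c("nanomolar", "micromolar", "none")
  if (!all(ok)) {
    abort(paste0("unknown affinity category: ",
                 paste(unique(evidence[!ok]), collapse = ", ")))
  }
  unname(c(nanomolar = "S", micromolar = "W", none = "N")[evidence])
}
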