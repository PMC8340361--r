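#' Consensus membrane-binding site windows
#'
#' The three membrane-docking elements shared across the PX superfamily are
#' represented as inclusive 1-based alignment-column ranges: site 1 is the
#' membrane-insertion loop between strands beta1 and beta2, site 2 runs from
#' the beta3 strand (with the RRY motif) into helix alpha1, and site 3 is the
#' loop holding the proline-rich element before helix alpha2. Windows must be
#' nonempty, in increasing order and non-overlapping.
#'
#' @param site1,site2,site3 Length-2 integer vectors `c(start, end)`.
#' @return A tibble with columns `site`, `start`, `end` and class
#'   `metstop_windows`.
#' @examples
#' site_windows(c(5, 10), c(15, 20), c(25, 30))
#' @export
site_windows <- function(site1, site2, site3) {
  w <- tibble(
    site = c("site1", "site2", "site3"),
    start = as.integer(c(site1[1], site2[1], site3[1])),
    end = as.integer(c(site1[2], site2[2], site3[2]))
  )
  if (any(is.na(w$start) | is.na(w$end)) || any(w$end < w$start) ||
      any(w$start < 1)) {
    abort("each window must be a nonempty 1-based inclusive range")
  }
  if (any(w$start[-1] <= w$end[-3])) {
    abort("windows must be non-overlapping and in increasing order")
  }
  class(w) <- c("metstop_windows", class(w))
  w
}

#' Read site windows from a YAML configuration
#'
#' Expects `sites: {site1: [a, b], site2: [c, d], site3: [e, f]}` with
#' 1-based inclusive alignment columns.
#'
#' @param path Path to a YAML file.
#' @return A `metstop_windows` tibble; see [site_windows()].
#' @export
read_site_windows <- function(path) {
  if (!file.exists(path)) abort(paste0("site config not found: ", path))
  cfg <- yaml::read_yaml(path)
  s <- cfg$sites
  if (is.null(s$site1) || is.null(s$site2) || is.null(s$site3)) {
    abort("YAML must define sites: site1, site2, site3")
  }
  site_windows(s$site1, s$site2, s$site3)
}

#' Write site windows to YAML
#'
#' @param windows A `metstop_windows` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_site_windows <- function(windows, path) {
  cfg <- list(sites = list(
    site1 = c(windows$start[1], windows$end[1]),
    site2 = c(windows$start[2], windows$end[2]),
    site3 = c(windows$start[3], windows$end[3])
  ))
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Packaged default site windows
#'
#' A reconstruction of the three consensus membrane-binding windows on the PX
#' superfamily alignment; the original column bounds were published only
#' descriptively, so analyses that depend on exact boundaries should supply
#' their own alignment-specific configuration.
#'
#' @return A `metstop_windows` tibble.
#' @export
default_site_windows <- function() {
  read_site_windows(system.file("extdata", "site_windows.yaml",
                                package = "metstop"))
}

# Alignment column of each ungapped sequence position.
position_to_column <- function(aligned_seq, position) {
  chars <- strsplit(aligned_seq, "")[[1]]
  cols <- which(chars != "-")
  if (any(position < 1 | position > length(cols))) {
    abort(paste0("position out of range (sequence has ", length(cols),
                 " residues)"))
  }
  cols[position]
}

#' Classify residues as inside or outside the membrane-binding sites
#'
#' Maps each ungapped sequence position to its alignment column and reports
#' which site window (if any) contains it.
#'
#' @param aligned_seq Aligned sequence (gaps as `-`).
#' @param position Integer vector of 1-based ungapped sequence positions.
#' @param windows A `metstop_windows` tibble.
#' @return Factor vector with levels site1, site2, site3, outside.
#' @examples
#' w <- site_windows(c(2, 4), c(6, 7), c(9, 10))
#' residue_site("MK-RLNDYWPA", c(2, 5), w)
#' @export
residue_site <- function(aligned_seq, position, windows) {
  cols <- position_to_column(aligned_seq, position)
  out <- rep("outside", length(cols))
  for (i in 1:3) {
    hit <- cols >= windows$start[i] & cols <= windows$end[i]
    out[hit] <- windows$site[i]
  }
  factor(out, levels = c("site1", "site2", "site3", "outside"))
}

#' Read a per-residue membrane-propensity profile
#'
#' CSV with columns `domain`, `position`, `score`: per-residue membrane
#' docking propensities from an external predictor. Scores strictly above the
#' threshold (default 30) flag a probable role in membrane docking.
#'
#' @param path Path to a CSV file.
#' @param threshold Docking-propensity threshold (default 30).
#' @return Tibble with columns `domain`, `position`, `score` and a
#'   `threshold` attribute.
#' @export
read_propensity <- function(path, threshold = 30) {
  if (!file.exists(path)) abort(paste0("propensity file not found: ", path))
  prof <- readr::read_csv(path, col_types = readr::cols(
    domain = "c", position = "i", score = "d"), progress = FALSE)
  attr(prof, "threshold") <- threshold
  prof
}

#' Is a scored residue membrane-interactive?
#'
#' `TRUE` iff the residue's propensity score strictly exceeds the threshold.
#'
#' @param profile Tibble with columns `position`, `score` (one domain), and
#'   optionally a `threshold` attribute.
#' @param position Integer vector of positions to test.
#' @param threshold Override for the profile's threshold (default 30).
#' @return Logical vector.
#' @export
membrane_interactive <- function(profile, position,
                                 threshold = attr(profile, "threshold") %||% 30) {
  idx <- match(position, profile$position)
  if (any(is.na(idx))) {
    abort(paste0("no propensity score for position(s) ",
                 paste(position[is.na(idx)], collapse = ", ")))
  }
  profile$score[idx] > threshold
}

#' Total propensity score over the membrane-binding sites
#'
#' Sums the per-residue propensity scores of all residues classified into any
#' of the three site windows. Residues inside the windows without a score are
#' treated as 0 with a warning.
#'
#' @param profile Tibble with columns `position`, `score` for this domain.
#' @param aligned_seq The domain's aligned sequence.
#' @param windows A `metstop_windows` tibble.
#' @return A single number.
#' @export
total_site_score <- function(profile, aligned_seq, windows) {
  n_res <- nchar(gsub("-", "", aligned_seq, fixed = TRUE))
  if (n_res == 0) return(0)
  sites <- residue_site(aligned_seq, seq_len(n_res), windows)
  inside <- which(sites != "outside")
  idx <- match(inside, profile$position)
  if (any(is.na(idx))) {
    warn(paste0(sum(is.na(idx)), " in-site residue(s) have no propensity ",
                "score; treated as 0"))
  }
  sum(profile$score[idx], na.rm = TRUE)
}

#' Lys/Arg inventory inside and outside the binding sites
#'
#' Counts lysine and arginine residues of a domain inside versus outside the
#' three site windows, and how many of each carry at least one metabolite
#' modification. Modified positions are counted once regardless of how many
#' records map there. `ptms` must carry a `position` column (sequence
#' positions, e.g. from [locate_in_sequence()]); only metabolite-type records
#' on K/R are considered.
#'
#' @param aligned_seq The domain's aligned sequence.
#' @param windows A `metstop_windows` tibble.
#' @param ptms PTM tibble with a `position` column (may have zero rows).
#' @return One-row tibble: `kr_inside`, `kr_inside_modified`, `kr_outside`,
#'   `kr_outside_modified`.
#' @export
kr_inventory <- function(aligned_seq, windows, ptms) {
  seq_chars <- strsplit(gsub("-", "", aligned_seq, fixed = TRUE), "")[[1]]
  n_res <- length(seq_chars)
  if (n_res == 0) {
    return(tibble(kr_inside = 0L, kr_inside_modified = 0L,
                  kr_outside = 0L, kr_outside_modified = 0L))
  }
  kr_pos <- which(toupper(seq_chars) %in% c("K", "R"))
  if (length(kr_pos) == 0) {
    return(tibble(kr_inside = 0L, kr_inside_modified = 0L,
                  kr_outside = 0L, kr_outside_modified = 0L))
  }
  inside <- residue_site(aligned_seq, kr_pos, windows) != "outside"
  mod_pos <- integer(0)
  if (nrow(ptms) > 0) {
    if (!"position" %in% names(ptms)) {
      abort("ptms must carry a 'position' column; run locate_in_sequence()")
    }
    met <- ptms$ptm_type %in% MET_PTM_TYPES & ptms$residue_letter %in% c("K", "R")
    mod_pos <- unique(ptms$position[met])
  }
  modified <- kr_pos %in% mod_pos
  tibble(
    kr_inside = sum(inside),
    kr_inside_modified = sum(inside & modified),
    kr_outside = sum(!inside),
    kr_outside_modified = sum(!inside & modified)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
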