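#' Parse a flanking nonamer
#'
#' Modification sites are written as 9-character windows with the modified
#' residue in lowercase at the center (position 5), e.g. `"VGRGrFTTY"` for a
#' methylated arginine. Terminal sites may be padded with `"-"`.
#'
#' @param flank Character vector of 9-character site strings.
#' @return Tibble with columns `center_letter` (uppercase) and `center_index`
#'   (always 5).
#' @examples
#' parse_flank("NHRYkHFDW")
#' @export
parse_flank <- function(flank) {
  if (any(nchar(flank) != 9)) {
    abort("flank strings must be exactly 9 characters")
  }
  chars <- stringr::str_split(flank, "", simplify = TRUE)
  is_lower <- matrix(chars %in% letters, nrow = nrow(chars))
  n_lower <- rowSums(is_lower)
  if (any(n_lower != 1)) {
    bad <- flank[n_lower != 1]
    abort(paste0("flank must contain exactly one lowercase letter: ",
                 paste(bad, collapse = ", ")))
  }
  idx <- apply(is_lower, 1, which)
  if (any(idx != 5)) {
    abort(paste0("lowercase (modified) residue must sit at the center ",
                 "(position 5): ", paste(flank[idx != 5], collapse = ", ")))
  }
  tibble(
    center_letter = toupper(chars[cbind(seq_along(flank), idx)]),
    center_index = as.integer(idx)
  )
}

#' Load a PTM site table
#'
#' Reads a tab-separated modification table with columns `protein`,
#' `species`, `residue` (letter + 1-based number, e.g. `"K92"`), `ptm_type`,
#' `flank` (nonamer, see [parse_flank()]) and optionally `study_count`
#' (unique reporting studies; defaults to 1). Every row is validated: the
#' residue token's letter must agree with the lowercase flank center,
#' metabolite modifications must sit on Lys or Arg, and phosphorylation on
#' Ser, Thr or Tyr.
#'
#' @param path Path to a TSV file.
#' @return Tibble with columns `protein`, `species`, `residue_letter`,
#'   `residue_number`, `ptm_type`, `flank`, `study_count`.
#' @examples
#' ptms <- px_ptm_table()
#' dplyr::count(ptms, ptm_type, sort = TRUE)
#' @export
load_ptm_table <- function(path) {
  if (!file.exists(path)) abort(paste0("PTM table not found: ", path))
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  required <- c("protein", "species", "residue", "ptm_type", "flank")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("PTM table is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  ptm_type <- tolower(raw$ptm_type)
  bad_type <- setdiff(unique(ptm_type), PTM_TYPES)
  if (length(bad_type) > 0) {
    abort(paste0("unknown ptm_type(s): ", paste(bad_type, collapse = ", ")))
  }
  m <- stringr::str_match(raw$residue, "^([A-Z])([0-9]+)$")
  bad_res <- which(is.na(m[, 1]))
  if (length(bad_res) > 0) {
    abort(paste0("malformed residue token in row(s) ",
                 paste(bad_res, collapse = ", ")))
  }
  residue_letter <- m[, 2]
  residue_number <- as.integer(m[, 3])
  centers <- parse_flank(raw$flank)
  mismatch <- which(centers$center_letter != residue_letter)
  if (length(mismatch) > 0) {
    abort(paste0("residue letter disagrees with flank center in row(s) ",
                 paste(mismatch, collapse = ", "), " (",
                 paste(paste0(raw$protein[mismatch], " ", raw$residue[mismatch],
                              " vs ", raw$flank[mismatch]), collapse = "; "),
                 ")"))
  }
  is_met <- ptm_type %in% MET_PTM_TYPES
  bad_chem <- which((is_met & !residue_letter %in% c("K", "R")) |
                      (!is_met & !residue_letter %in% c("S", "T", "Y")))
  if (length(bad_chem) > 0) {
    abort(paste0("modification chemistry incompatible with residue in row(s) ",
                 paste(bad_chem, collapse = ", ")))
  }
  study_count <- if ("study_count" %in% names(raw)) {
    sc <- suppressWarnings(as.integer(raw$study_count))
    if (any(is.na(sc) | sc < 1)) {
      abort("study_count must be a positive integer")
    }
    sc
  } else {
    rep(1L, nrow(raw))
  }
  tibble(
    protein = raw$protein,
    species = raw$species,
    residue_letter = residue_letter,
    residue_number = residue_number,
    ptm_type = ptm_type,
    flank = raw$flank,
    study_count = study_count
  )
}

#' Write a PTM site table
#'
#' @param ptms A PTM tibble as returned by [load_ptm_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ptm_table <- function(ptms, path) {
  out <- tibble(
    protein = ptms$protein,
    species = ptms$species,
    residue = paste0(ptms$residue_letter, ptms$residue_number),
    ptm_type = ptms$ptm_type,
    flank = ptms$flank,
    study_count = ptms$study_count
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Packaged PX-domain modification table
#'
#' The transcription of the published table of metabolite-based modifications
#' of PX-domain membrane-binding sites: 86 records across nine species, each
#' with its flanking nonamer. Per-modification study counts were not
#' published, so every row carries `study_count = 1`.
#'
#' @return An 86-row tibble; see [load_ptm_table()] for columns.
#' @export
px_ptm_table <- function() {
  path <- system.file("extdata", "px_ptms.tsv", package = "metstop")
  load_ptm_table(path)
}

#' Aggregate modification records to unique modifications
#'
#' A "modification" is identified by (protein, species, residue_number,
#' ptm_type); rows sharing that key (e.g. the same site harvested from
#' several databases) are pooled by taking the maximum study count, so each
#' original study is counted once per modification.
#'
#' @param ptms A PTM tibble.
#' @return A tibble with one row per unique modification.
#' @export
aggregate_ptms <- function(ptms) {
  ptms %>%
    group_by(.data$protein, .data$species, .data$residue_number,
             .data$ptm_type) %>%
    summarise(
      residue_letter = .data$residue_letter[1],
      flank = .data$flank[1],
      study_count = max(.data$study_count),
      .groups = "drop"
    ) %>%
    select("protein", "species", "residue_letter", "residue_number",
           "ptm_type", "flank", "study_count")
}

#' Anchor modification records onto a sequence
#'
#' Verifies each record against an ungapped amino-acid sequence: the residue
#' letter must sit at `residue_number - numbering_offset` and the surrounding
#' 9-residue window must match the record's flank (tolerating `"-"` padding
#' where the window runs off either terminus). If the stated position fails
#' but the flank matches elsewhere, the mismatch is reported as an ambiguity
#' listing candidate positions.
#'
#' @param ptms A PTM tibble (records for the protein `sequence` belongs to).
#' @param sequence Ungapped amino-acid string.
#' @param numbering_offset Integer such that sequence position 1 corresponds
#'   to source residue number `numbering_offset + 1`.
#' @return The input tibble with added columns `position` (1-based sequence
#'   position) and `verified` (logical).
#' @export
locate_in_sequence <- function(ptms, sequence, numbering_offset = 0L) {
  if (nchar(sequence) == 0) abort("sequence is empty")
  n <- nchar(sequence)
  window_at <- function(pos) {
    lo <- pos - 4L; hi <- pos + 4L
    left_pad <- max(0L, 1L - lo)
    right_pad <- max(0L, hi - n)
    core <- substr(sequence, max(1L, lo), min(n, hi))
    paste0(strrep("-", left_pad), toupper(core), strrep("-", right_pad))
  }
  flank_matches <- function(flank, pos) {
    win <- window_at(pos)
    fl <- toupper(flank)
    ok <- TRUE
    for (i in 1:9) {
      a <- substr(fl, i, i); b <- substr(win, i, i)
      if (a != "-" && b != "-" && a != b) { ok <- FALSE; break }
      if (xor(a == "-", b == "-")) { ok <- FALSE; break }
    }
    ok
  }
  positions <- integer(nrow(ptms))
  verified <- logical(nrow(ptms))
  for (i in seq_len(nrow(ptms))) {
    pos <- ptms$residue_number[i] - numbering_offset
    flank <- ptms$flank[i]
    letter <- ptms$residue_letter[i]
    in_range <- pos >= 1 && pos <= n
    ok_here <- in_range &&
      toupper(substr(sequence, pos, pos)) == letter &&
      flank_matches(flank, pos)
    if (ok_here) {
      positions[i] <- pos; verified[i] <- TRUE
      next
    }
    # stated position fails; scan for the flank elsewhere
    candidates <- which(
      strsplit(toupper(sequence), "")[[1]] == letter &
        map_lgl(seq_len(n), function(p) flank_matches(flank, p))
    )
    candidates <- setdiff(candidates, pos)
    if (length(candidates) > 0) {
      abort(paste0(
        "record ", ptms$protein[i], " ", letter, ptms$residue_number[i],
        ": flank does not verify at the stated position but matches at ",
        "sequence position(s) ", paste(candidates, collapse = ", "),
        " (possible numbering-offset error)"
      ))
    }
    abort(paste0(
      "record ", ptms$protein[i], " ", letter, ptms$residue_number[i],
      ": residue/flank does not match the sequence at position ", pos
    ))
  }
  ptms$position <- positions
  ptms$verified <- verified
  ptms
}
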