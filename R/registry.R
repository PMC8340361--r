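#' Load a PX-domain feature table
#'
#' Reads a tab-separated feature table with one row per PX domain: its
#' phosphoinositide ligand codes, Lipid Specificity Index (LSI), MET-stop
#' score (MSS), PIP-stop score (PSS), Membrane Affinity Index (MAI) and
#' average mRNA expression level. The cell value `"nd"` marks a value that has
#' not been experimentally determined and becomes `NA` (for ligands, an `NA`
#' list element); a ligand cell of `"0"` means the domain binds no
#' phosphoinositide (empty ligand set, LSI 0).
#'
#' Required columns: `name`, `ligands` (comma-joined codes among
#' 3/4/5/34/35/45/345, or "0", or "nd"), `lsi`, `mss`, `pss`, `mai`
#' (S/W/N or "nd"), `expression`, `structure`. Extra columns (e.g. a
#' provenance `note`) are carried through.
#'
#' @param path Path to a TSV file.
#' @param strict If `TRUE` (default) any malformed cell aborts the load;
#'   otherwise malformed numeric cells become `NA` with a warning.
#' @return A tibble with one row per domain. `ligands` is a list-column of
#'   character vectors (`character(0)` = non-binder, `NA` = undetermined).
#' @examples
#' px <- px_domain_table()
#' nrow(px)
#' @export
load_domain_table <- function(path, strict = TRUE) {
  if (!file.exists(path)) {
    abort(paste0("domain table not found: ", path))
  }
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  required <- c("name", "ligands", "lsi", "mss", "pss", "mai",
                "expression", "structure")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("domain table is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(raw) == 0) {
    warn("domain table contains a header but no rows")
  }
  dup <- raw$name[duplicated(raw$name)]
  if (length(dup) > 0) {
    abort(paste0("duplicate domain name(s): ", paste(unique(dup), collapse = ", ")))
  }

  parse_ligands <- function(cell, row, name) {
    if (is.na(cell) || identical(cell, "nd")) return(NA_character_)
    if (identical(cell, "0")) return(character(0))
    codes <- strsplit(cell, ",", fixed = TRUE)[[1]]
    codes <- trimws(codes)
    bad <- setdiff(codes, PIP_CODES)
    if (length(bad) > 0) {
      abort(paste0("row ", row, " (", name, "): unknown ligand code(s): ",
                   paste(bad, collapse = ", ")))
    }
    if (anyDuplicated(codes)) {
      abort(paste0("row ", row, " (", name, "): duplicated ligand code"))
    }
    codes
  }

  num_col <- function(x, colname, integer = FALSE) {
    x[x == "nd"] <- NA_character_
    parsed <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & is.na(parsed))
    if (length(bad) > 0) {
      msg <- paste0("malformed ", colname, " cell in row(s) ",
                    paste(bad, collapse = ", "))
      if (strict) abort(msg) else warn(msg)
    }
    if (integer) as.integer(round(parsed)) else parsed
  }

  out <- tibble(
    name = raw$name,
    ligands = map(seq_len(nrow(raw)),
                  function(i) parse_ligands(raw$ligands[[i]], i, raw$name[[i]])),
    lsi = num_col(raw$lsi, "lsi", integer = TRUE),
    mss = num_col(raw$mss, "mss", integer = TRUE),
    pss = num_col(raw$pss, "pss", integer = TRUE),
    mai = ifelse(raw$mai %in% c("S", "W", "N"), raw$mai, NA_character_),
    expression = num_col(raw$expression, "expression"),
    structure = raw$structure
  )
  bad_mai <- which(!is.na(raw$mai) & raw$mai != "nd" & !raw$mai %in% c("S", "W", "N"))
  if (length(bad_mai) > 0) {
    msg <- paste0("unknown MAI label in row(s) ", paste(bad_mai, collapse = ", "))
    if (strict) abort(msg) else warn(msg)
  }
  neg <- which(out$mss < 0 | out$pss < 0 | out$expression < 0)
  if (length(neg) > 0) {
    abort(paste0("negative score/expression in row(s) ", paste(neg, collapse = ", ")))
  }
  extra <- setdiff(names(raw), required)
  for (col in extra) out[[col]] <- raw[[col]]
  inform(paste0("loaded ", nrow(out), " domain record(s) from ", basename(path)))
  out
}

#' Write a PX-domain feature table
#'
#' Inverse of [load_domain_table()]: serialises the tibble back to the TSV
#' dialect (`"nd"` for undetermined cells, `"0"` for empty ligand sets) so
#' that a load/write/load round trip is lossless.
#'
#' @param domains A tibble as returned by [load_domain_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_domain_table <- function(domains, path) {
  enc <- function(x) ifelse(is.na(x), "nd", as.character(x))
  lig <- map_chr(domains$ligands, function(l) {
    if (length(l) == 1 && is.na(l)) "nd"
    else if (length(l) == 0) "0"
    else paste(l, collapse = ",")
  })
  out <- tibble(
    name = domains$name,
    ligands = lig,
    lsi = enc(domains$lsi),
    mss = enc(domains$mss),
    pss = enc(domains$pss),
    mai = enc(domains$mai),
    expression = enc(domains$expression),
    structure = domains$structure
  )
  extra <- setdiff(names(domains),
                   c("name", "ligands", "lsi", "mss", "pss", "mai",
                     "expression", "structure"))
  for (col in extra) out[[col]] <- domains[[col]]
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Packaged human PX-domain feature table
#'
#' The transcription of the published human PX-domain property table:
#' 50 domains (the two NOXO1 splice forms counted separately) with ligand
#' codes, LSI, MSS, PSS, MAI and average expression. Greek letters in protein
#' names are ASCII-folded (NOXO1b, NOXO1g, PIK3C2a/b/g, p40phox, p47phox).
#' The SNX30 and SNX33 LSI values were inferred from SNX7 and SNX18 rather
#' than measured; their rows carry `note == "inferred"`.
#'
#' @return A 50-row tibble; see [load_domain_table()] for columns.
#' @examples
#' summarize_classes(px_domain_table())
#' @export
px_domain_table <- function() {
  path <- system.file("extdata", "px_domains.tsv", package = "metstop")
  suppressMessages(load_domain_table(path))
}

#' Check the stored LSI column against recomputation from ligand sets
#'
#' Recomputes the Lipid Specificity Index from each domain's ligand codes via
#' [compute_lsi()] and compares it with the stored `lsi` column. Rows with an
#' undetermined ligand set are skipped.
#'
#' @param domains A domain feature tibble.
#' @return A tibble with columns `name`, `lsi_stored`, `lsi_recomputed`,
#'   `match`; one row per ligand-determined domain.
#' @examples
#' rep <- verify_lsi_column(px_domain_table())
#' sum(!rep$match)  # 0
#' @export
verify_lsi_column <- function(domains) {
  determined <- map_lgl(domains$ligands, function(l) {
    !(length(l) == 1 && is.na(l))
  })
  sub <- domains[determined, ]
  recomputed <- map_int(sub$ligands, function(l) compute_lsi(l)$lsi)
  tibble(
    name = sub$name,
    lsi_stored = sub$lsi,
    lsi_recomputed = recomputed,
    match = !is.na(sub$lsi) & sub$lsi == recomputed
  )
}
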