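#' Configuration for the synthetic-data generator
#'
#' Bundles the knobs of the generator that emulates the study's inputs: a set
#' of domain sequences with K/R residues scattered inside and outside three
#' membrane-binding site windows, metabolite modifications planted with a
#' configurable inside-site enrichment, study counts with a skewed law, and a
#' feature table with a chosen latent correlation structure.
#'
#' @param n_domains Number of domains (default 50, the size of the human
#'   PX-domain family table).
#' @param sequence_length Residues per domain (default 120, a typical PX
#'   domain).
#' @param site_fraction Fraction of columns covered by the three windows
#'   (default 0.25).
#' @param kr_density Probability a position is Lys or Arg (default 0.3,
#'   matching the basic-residue-rich character of the binding sites).
#' @param enrichment Ratio of the per-residue modification probability inside
#'   sites to outside (`rho`; 1 = null, default 3).
#' @param base_mod_rate Probability an outside K/R is modified (default 0.1).
#' @param study_count_law List: `law = "poisson1"` (1 + Poisson(lambda),
#'   skewed like citation counts but reaching every weight bin) or
#'   `law = "constant"` with `value`; default Poisson with `lambda = 1`.
#' @param feature_correlations 4x4 target latent correlation matrix for
#'   (mss, pss, lsi, expression); defaults to the correlation pattern of the
#'   published feature table.
#' @param seed Integer seed; one seed drives every draw.
#' @return A list of class `metstop_synth_config`.
#' @export
synth_config <- function(n_domains = 50, sequence_length = 120,
                         site_fraction = 0.25, kr_density = 0.3,
                         enrichment = 3, base_mod_rate = 0.1,
                         study_count_law = list(law = "poisson1", lambda = 1),
                         feature_correlations = default_feature_correlations(),
                         seed = 1L) {
  probs <- c(site_fraction = site_fraction, kr_density = kr_density,
             base_mod_rate = base_mod_rate)
  if (any(probs < 0 | probs > 1)) {
    abort("site_fraction, kr_density and base_mod_rate must lie in [0, 1]")
  }
  if (enrichment < 0) abort("enrichment must be nonnegative")
  if (n_domains < 2) abort("n_domains must be at least 2")
  if (round(site_fraction * sequence_length) < 3) {
    abort("infeasible config: windows would cover fewer than 3 columns")
  }
  if (enrichment * base_mod_rate > 1) {
    abort("infeasible config: inside-site modification rate exceeds 1")
  }
  structure(
    list(n_domains = as.integer(n_domains),
         sequence_length = as.integer(sequence_length),
         site_fraction = site_fraction, kr_density = kr_density,
         enrichment = enrichment, base_mod_rate = base_mod_rate,
         study_count_law = study_count_law,
         feature_correlations = feature_correlations,
         seed = as.integer(seed)),
    class = "metstop_synth_config"
  )
}

#' Default target correlation matrix for synthetic feature tables
#'
#' Latent pairwise correlations for (mss, pss, lsi, expression) shaped like
#' the published feature table's empirical pattern.
#'
#' @return A symmetric positive-definite 4x4 matrix.
#' @export
default_feature_correlations <- function() {
  vars <- c("mss", "pss", "lsi", "expression")
  m <- diag(4)
  dimnames(m) <- list(vars, vars)
  m["mss", "pss"] <- m["pss", "mss"] <- 0.3851
  m["mss", "lsi"] <- m["lsi", "mss"] <- 0.0809
  m["mss", "expression"] <- m["expression", "mss"] <- 0.3637
  m["pss", "lsi"] <- m["lsi", "pss"] <- 0.3143
  m["pss", "expression"] <- m["expression", "pss"] <- 0.4843
  m["lsi", "expression"] <- m["expression", "lsi"] <- 0.10
  m
}

# Deterministic window layout: three near-equal windows, one centered in each
# third of the alignment, covering round(site_fraction * length) columns.
synth_windows <- function(sequence_length, site_fraction) {
  total <- round(site_fraction * sequence_length)
  sizes <- rep(total %/% 3, 3)
  extra <- total - sum(sizes)
  if (extra >= 1) sizes[1] <- sizes[1] + 1L
  if (extra == 2) sizes[2] <- sizes[2] + 1L
  block <- sequence_length / 3
  starts <- vapply(1:3, function(i) {
    floor((i - 1) * block) + max(1L, floor((block - sizes[i]) / 2)) + 1L
  }, numeric(1))
  site_windows(c(starts[1], starts[1] + sizes[1] - 1),
               c(starts[2], starts[2] + sizes[2] - 1),
               c(starts[3], starts[3] + sizes[3] - 1))
}

draw_study_counts <- function(n, law) {
  if (identical(law$law, "constant")) {
    rep(as.integer(law$value %||% 1L), n)
  } else if (identical(law$law, "poisson1")) {
    1L + rpois(n, law$lambda %||% 1)
  } else {
    abort(paste0("unknown study_count_law: ", law$law))
  }
}

#' Generate a synthetic domain set with known ground truth
#'
#' Draws `n_domains` amino-acid sequences of equal length with K/R placed at
#' `kr_density`, lays the three site windows over the columns, and plants
#' metabolite modifications on K/R residues with probability
#' `base_mod_rate * enrichment` inside the windows and `base_mod_rate`
#' outside. Sequences are generated gap-free at one length, so the emitted
#' alignment is the sequences themselves and residue positions coincide with
#' alignment columns. Fully deterministic given `config$seed`.
#'
#' @param config A [synth_config()].
#' @return A list with `sequences` (named character vector), `alignment`
#'   (identical here), `windows`, `truth` (tibble: domain, position, letter,
#'   region, modified, ptm_type, study_count -- one row per K/R position) and
#'   `config`.
#' @export
gen_domain_set <- function(config) {
  stopifnot(inherits(config, "metstop_synth_config"))
  L <- config$sequence_length
  nd <- config$n_domains
  windows <- synth_windows(L, config$site_fraction)
  other_aa <- setdiff(strsplit("ACDEFGHILMNPQSTVWY", "")[[1]], character(0))
  p_in <- min(1, config$enrichment * config$base_mod_rate)
  p_out <- config$base_mod_rate
  withr::with_seed(config$seed, {
    in_site <- rep(FALSE, L)
    for (i in 1:3) in_site[windows$start[i]:windows$end[i]] <- TRUE
    # one position-by-domain letter matrix, drawn in a single pass
    is_kr <- matrix(runif(L * nd) < config$kr_density, nrow = L)
    M <- matrix("", nrow = L, ncol = nd)
    n_kr <- sum(is_kr)
    M[is_kr] <- sample(c("K", "R"), n_kr, replace = TRUE)
    M[!is_kr] <- sample(other_aa, L * nd - n_kr, replace = TRUE)
    seqs <- apply(M, 2, paste, collapse = "")
    names(seqs) <- sprintf("synth%03d", seq_len(nd))
    kr_idx <- which(is_kr, arr.ind = TRUE)
    ord <- order(kr_idx[, 2], kr_idx[, 1])
    pos <- kr_idx[ord, 1]
    dom <- kr_idx[ord, 2]
    inside <- in_site[pos]
    modified <- runif(length(pos)) < ifelse(inside, p_in, p_out)
    ptm_type <- rep(NA_character_, length(pos))
    study_count <- rep(NA_integer_, length(pos))
    if (any(modified)) {
      ptm_type[modified] <- sample(MET_PTM_TYPES, sum(modified), replace = TRUE)
      study_count[modified] <- draw_study_counts(sum(modified),
                                                 config$study_count_law)
    }
    truth <- tibble(
      domain = names(seqs)[dom],
      position = as.integer(pos),
      letter = M[cbind(pos, dom)],
      region = ifelse(inside, "inside", "outside"),
      modified = modified,
      ptm_type = ptm_type,
      study_count = study_count
    )
    list(sequences = seqs, alignment = seqs, windows = windows,
         truth = truth, config = config)
  })
}

#' Emit a PTM table from a synthetic domain set
#'
#' Formats every planted modification in the truth record as a PTM record in
#' the standard table dialect: flanking nonamers are cut from the true
#' sequences with the modified residue lowercased at the center and `-`
#' padding at the termini. Purely deterministic given the domain set (no
#' further random draws), and every row passes [load_ptm_table()] validation
#' by construction.
#'
#' @param domain_set Output of [gen_domain_set()].
#' @return A PTM tibble in the [load_ptm_table()] column layout.
#' @export
gen_ptm_table <- function(domain_set) {
  mods <- dplyr::filter(domain_set$truth, .data$modified)
  if (nrow(mods) == 0) {
    return(tibble(protein = character(), species = character(),
                  residue_letter = character(), residue_number = integer(),
                  ptm_type = character(), flank = character(),
                  study_count = integer()))
  }
  flanks <- map2_chr(mods$domain, mods$position, function(d, pos) {
    s <- domain_set$sequences[[d]]
    n <- nchar(s)
    lo <- pos - 4L; hi <- pos + 4L
    core <- substr(s, max(1L, lo), min(n, hi))
    win <- paste0(strrep("-", max(0L, 1L - lo)), core,
                  strrep("-", max(0L, hi - n)))
    substr(win, 5, 5) <- tolower(substr(win, 5, 5))
    win
  })
  tibble(
    protein = mods$domain,
    species = "synthetic",
    residue_letter = mods$letter,
    residue_number = mods$position,
    ptm_type = mods$ptm_type,
    flank = flanks,
    study_count = mods$study_count
  )
}

#' Generate a synthetic domain feature table
#'
#' Draws latent multivariate-normal (mss, pss, lsi, expression) vectors with
#' the configured correlation matrix, then integerises: mss and pss are
#' rounded latent Gaussians truncated at 0, lsi is rounded and clamped to
#' 0..10, expression is truncated at 0 and left continuous. The attribute
#' `truth` stores the latent (pre-truncation) correlation matrix, since
#' truncation and rounding shrink the observable correlations slightly.
#'
#' @param config A [synth_config()]; `feature_correlations` must be positive
#'   definite.
#' @param n Number of rows (defaults to `config$n_domains`).
#' @return Tibble with columns `name`, `lsi`, `mss`, `pss`, `expression` and
#'   a `truth` attribute.
#' @export
gen_feature_table <- function(config, n = config$n_domains) {
  R <- config$feature_correlations
  ch <- tryCatch(chol(R), error = function(e) {
    abort("feature_correlations is not positive definite")
  })
  mu <- c(mss = 4, pss = 4, lsi = 5.5, expression = 20)
  sdv <- c(mss = 2.5, pss = 2.5, lsi = 2.5, expression = 15)
  withr::with_seed(config$seed, {
    z <- matrix(rnorm(n * 4), nrow = n) %*% ch
    lat <- sweep(sweep(z, 2, sdv, "*"), 2, mu, "+")
    out <- tibble(
      name = sprintf("synth%03d", seq_len(n)),
      lsi = as.integer(pmin(10, pmax(0, round(lat[, 3])))),
      mss = as.integer(round(pmax(0, lat[, 1]))),
      pss = as.integer(round(pmax(0, lat[, 2]))),
      expression = pmax(0, lat[, 4])
    )
  })
  attr(out, "truth") <- list(latent_correlations = R, latent_means = mu,
                             latent_sds = sdv)
  out
}

#' Per-domain modified K/R proportions of a synthetic domain set
#'
#' From the truth record: the fraction of K/R residues carrying a planted
#' modification, inside versus outside the site windows, per domain. Domains
#' with no K/R on one side are dropped (with a message) since their
#' proportion is undefined.
#'
#' @param domain_set Output of [gen_domain_set()].
#' @return Tibble: `domain`, `p_inside`, `p_outside`.
#' @export
kr_proportions <- function(domain_set) {
  props <- domain_set$truth %>%
    group_by(.data$domain, .data$region) %>%
    summarise(p = mean(.data$modified), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "region", values_from = "p",
                       names_prefix = "p_")
  if (!"p_inside" %in% names(props)) props$p_inside <- NA_real_
  if (!"p_outside" %in% names(props)) props$p_outside <- NA_real_
  complete <- !is.na(props$p_inside) & !is.na(props$p_outside)
  if (any(!complete)) {
    inform(paste0(sum(!complete), " domain(s) dropped: no K/R on one side"))
  }
  props[complete, c("domain", "p_inside", "p_outside")]
}

#' Monte-Carlo calibration of the inside/outside enrichment test
#'
#' Repeatedly generates domain sets under `config` (varying the seed as
#' `config$seed + replicate`) and applies the paired t-test to the per-domain
#' inside vs outside modified-K/R proportions. With `enrichment = 1` the
#' rejection rate estimates the type-I error; with `enrichment > 1` it
#' estimates power.
#'
#' @param config A [synth_config()].
#' @param n_reps Number of replicates.
#' @param alpha Significance level (default 0.05).
#' @return Tibble with one row per replicate: `rep`, `t`, `df`, `p`,
#'   `reject`.
#' @export
simulate_enrichment_test <- function(config, n_reps, alpha = 0.05) {
  res <- map(seq_len(n_reps), function(r) {
    cfg <- config
    cfg$seed <- config$seed + r
    ds <- gen_domain_set(cfg)
    props <- suppressMessages(kr_proportions(ds))
    tt <- paired_t(props$p_inside, props$p_outside)
    tibble(rep = r, t = tt$t, df = tt$df, p = tt$p, reject = tt$p < alpha)
  })
  bind_rows(res)
}

#' Write a synthetic domain set to disk
#'
#' Emits the standard input files: `sequences.fasta`, `alignment.fasta`,
#' `sites.yaml`, `ptms.tsv` and `truth.tsv`.
#'
#' @param domain_set Output of [gen_domain_set()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_domain_set <- function(domain_set, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_fasta(domain_set$sequences, file.path(dir, "sequences.fasta"))
  write_fasta(domain_set$alignment, file.path(dir, "alignment.fasta"))
  write_site_windows(domain_set$windows, file.path(dir, "sites.yaml"))
  write_ptm_table(gen_ptm_table(domain_set), file.path(dir, "ptms.tsv"))
  readr::write_tsv(domain_set$truth, file.path(dir, "truth.tsv"),
                   progress = FALSE)
  invisible(dir)
}
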