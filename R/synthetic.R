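#' Configuration for the synthetic NanoString-like cohort simulator
#'
#' Describes a cohort with the statistical structure the cascade
#' classifier assumes: per-entity blocks of upregulated marker genes,
#' flat background genes, stable housekeeping genes, log-normal
#' library-size variation, negative-binomial count noise, and
#' tumor-purity mixing of each tumor profile with a nonmalignant
#' background profile. Entity-conditional genetic-marker prevalences
#' drive [simulate_marker_status()].
#'
#' @param entities entity names (default the six SBCLN entities).
#' @param samples_per_entity scalar or per-entity vector of sample counts.
#' @param n_controls number of nonmalignant control samples.
#' @param markers_per_entity planted upregulated markers per entity
#'   (default 8).
#' @param n_background flat background genes (default 60).
#' @param n_housekeeping stable housekeeping genes (default 6).
#' @param effect marker log2 effect size over baseline (default 2).
#' @param baseline baseline mean count of endogenous genes (default 200).
#' @param hk_baseline mean count of housekeeping genes (default 500).
#' @param dispersion negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2); 0 gives Poisson counts. Default 0.1.
#' @param libsize_sd sd of the log-normal per-sample library factor
#'   (default 0.2).
#' @param purity tumor cell content: a single value (fixed), a length-2
#'   range (uniform), or one value per tumor sample. Default
#'   `c(0.9, 1)`, emulating a highly purified training cohort.
#' @param prevalences named list: per genetic marker, a named vector of
#'   entity-conditional positivity rates plus a `default` rate for
#'   unlisted entities. Controls are always negative.
#' @param ffpe_fraction fraction of samples typed FFPE (default 0.85).
#' @param seed integer seed.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(entities = SBCLN_ENTITIES,
                             samples_per_entity = 20,
                             n_controls = 40,
                             markers_per_entity = 8,
                             n_background = 60,
                             n_housekeeping = 6,
                             effect = 2,
                             baseline = 200,
                             hk_baseline = 500,
                             dispersion = 0.1,
                             libsize_sd = 0.2,
                             purity = c(0.9, 1),
                             prevalences = NULL,
                             ffpe_fraction = 0.85,
                             seed = 1L) {
  if (effect <= 0) stop("effect size must be positive")
  if (dispersion < 0) stop("dispersion must be nonnegative")
  n_ent <- length(entities)
  samples_per_entity <- rep_len(samples_per_entity, n_ent)
  if (any(samples_per_entity < 1) || n_controls < 1)
    stop("at least one sample per class required")
  if (is.null(prevalences)) {
    prevalences <- list(
      IGH_BCL2    = c("FL" = 0.8, default = 0.03),
      MYD88_L265P = c("LPL/WM" = 0.9, default = 0.05),
      BRAF_V600E  = c("HCL" = 0.9, default = 0.05),
      EZH2_Y646   = c("FL" = 0.15, default = 0.05))
  }
  for (p in prevalences)
    if (any(p < 0 | p > 1)) stop("prevalences must lie in [0,1]")
  structure(list(entities = entities,
                 samples_per_entity = samples_per_entity,
                 n_controls = n_controls,
                 markers_per_entity = markers_per_entity,
                 n_background = n_background,
                 n_housekeeping = n_housekeeping,
                 effect = effect, baseline = baseline,
                 hk_baseline = hk_baseline,
                 dispersion = dispersion, libsize_sd = libsize_sd,
                 purity = purity, prevalences = prevalences,
                 ffpe_fraction = ffpe_fraction,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Planted marker genes of a synthetic configuration
#'
#' @param config a [synthetic_config()].
#' @return named list (by entity) of the marker gene names the simulator
#'   plants for each entity.
#' @export
planted_markers <- function(config) {
  out <- lapply(seq_along(config$entities), function(i)
    paste0("E", i, "_M", seq_len(config$markers_per_entity)))
  names(out) <- config$entities
  out
}

.draw_counts <- function(mu, dispersion) {
  if (dispersion == 0) stats::rpois(length(mu), mu)
  else stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion)
}

#' Simulate a NanoString-like cohort
#'
#' Draws raw counts gene-by-sample. For endogenous gene g in a tumor
#' sample s of entity e with purity rho, the mean is
#' `L_s * (rho * mu_ge + (1 - rho) * baseline)` where
#' `mu_ge = baseline * 2^effect` when g is a planted marker of e and
#' `baseline` otherwise; controls use the pure background profile.
#' Housekeeping genes have mean `L_s * hk_baseline` in every class.
#' `L_s` is a log-normal library factor and counts are negative-binomial.
#' Genetic-marker status is filled by [simulate_marker_status()].
#' Fully reproducible from `config$seed`.
#'
#' @param config a [synthetic_config()].
#' @return list with `counts` (a [count_matrix()]), `annotation` (a
#'   `sample_annotation` data.frame), and `markers` (the planted marker
#'   lists, [planted_markers()]).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  ents <- config$entities
  mk <- planted_markers(config)
  marker_genes <- unlist(mk, use.names = FALSE)
  bg_genes <- if (config$n_background)
    paste0("BG", seq_len(config$n_background)) else character()
  hk_genes <- if (config$n_housekeeping)
    paste0("HK", seq_len(config$n_housekeeping)) else character()
  genes <- c(marker_genes, bg_genes, hk_genes)
  n_endo <- length(marker_genes) + length(bg_genes)

  label <- c(rep(ents, config$samples_per_entity),
             rep("control", config$n_controls))
  n <- length(label)
  sample_id <- sprintf("S%03d", seq_len(n))
  n_tumor <- n - config$n_controls

  pur <- config$purity
  rho <- if (length(pur) == 1L) rep(pur, n_tumor)
         else if (length(pur) == 2L) stats::runif(n_tumor, pur[1], pur[2])
         else if (length(pur) == n_tumor) pur
         else stop("purity must be length 1, 2, or one per tumor sample")
  if (any(rho < 0 | rho > 1)) stop("purity values must lie in [0,1]")
  rho_all <- c(rho, rep(0, config$n_controls))

  L <- stats::rlnorm(n, meanlog = 0, sdlog = config$libsize_sd)

  # per-gene tumor-profile means for each entity
  mu_entity <- matrix(config$baseline, n_endo, length(ents),
                      dimnames = list(c(marker_genes, bg_genes), ents))
  for (e in ents)
    mu_entity[mk[[e]], e] <- config$baseline * 2^config$effect

  counts <- matrix(0L, length(genes), n,
                   dimnames = list(genes, sample_id))
  for (s in seq_len(n)) {
    if (label[s] == "control") {
      mu_endo <- rep(config$baseline, n_endo)
    } else {
      mu_endo <- rho_all[s] * mu_entity[, label[s]] +
        (1 - rho_all[s]) * config$baseline
    }
    mu <- L[s] * c(mu_endo, rep(config$hk_baseline, length(hk_genes)))
    counts[, s] <- as.integer(.draw_counts(mu, config$dispersion))
  }

  role <- c(rep("endogenous", n_endo),
            rep("housekeeping_candidate", length(hk_genes)))
  ann <- data.frame(
    sample_id = sample_id,
    cohort = "training",
    label = label,
    tumor_cell_content = ifelse(label == "control", NA, rho_all),
    sample_type = ifelse(stats::runif(n) < config$ffpe_fraction,
                         "FFPE", "fresh_frozen"),
    stringsAsFactors = FALSE)
  ann <- simulate_marker_status(as_sample_annotation(ann), config)
  list(counts = count_matrix(counts, gene_role = role),
       annotation = ann,
       markers = mk)
}

#' Fill genetic-marker status by entity-conditional prevalences
#'
#' Independent Bernoulli draws per sample and marker at the configured
#' conditional prevalence of the sample's entity (the `default` rate for
#' unlisted entities); control samples are always negative. Reproducible
#' given the RNG state; [simulate_cohort()] calls this under its own
#' seed.
#'
#' @param annotations a `sample_annotation` data.frame with a `label`
#'   column.
#' @param config a [synthetic_config()] carrying `prevalences`.
#' @return the annotations with one positive/negative column per marker.
#' @export
simulate_marker_status <- function(annotations, config) {
  for (m in names(config$prevalences)) {
    pv <- config$prevalences[[m]]
    p <- vapply(annotations$label, function(l) {
      if (l == "control") 0
      else if (l %in% names(pv)) unname(pv[l])
      else unname(pv["default"])
    }, 0)
    annotations[[m]] <- ifelse(stats::runif(nrow(annotations)) < p,
                               "positive", "negative")
  }
  annotations
}
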