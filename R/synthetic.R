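#' Generative-model parameters for a synthetic flow sample
#'
#' Describes one simulated acquisition of the dual-fluorescence P2A
#' reporter assay. Each recorded event is either a live reporter cell or
#' a debris particle. A live cell expresses the bicistronic reporter at a
#' per-cell level `E ~ LogNormal(expr_mu, expr_sigma)`; ribosomal P2A
#' skipping yields exactly one free GFP per client-mCherry fusion, so
#' before degradation both channels see the same molecule count. Client
#' degradation multiplies the mCherry signal by the fold change `phi`
#' (`phi = 1` is wild-type-like stability, `phi < 1` destabilized,
#' `phi > 1` stabilized):
#'
#' \deqn{GFP = E \cdot g_{scale} \cdot \epsilon_G + a_G, \qquad
#'       mCherry = E \cdot \phi \cdot r_{scale} \cdot \epsilon_R + a_R}
#'
#' with independent multiplicative log-normal channel noise
#' \eqn{\epsilon} of coefficient of variation `noise_cv` (unit mean), and
#' additive autofluorescence backgrounds \eqn{a_G, a_R}. Debris events
#' carry autofluorescence only and sit in a scatter cluster whose median
#' FSC is well below the live cluster, so scatter gating has an
#' unambiguous ground truth. Fluorophore brightness and detector gain are
#' absorbed into the channel scale constants: the downstream pipeline
#' only consumes ratios normalized to a wild-type reference, so absolute
#' units are arbitrary by design.
#'
#' @param n_cells Number of events to record (default 20000, the
#'   acquisition depth the assay targets per sample).
#' @param live_fraction Expected fraction of events in the live
#'   population, in `[0, 1]`.
#' @param expr_mu,expr_sigma Natural-log mean and sd of per-cell
#'   expression `E`.
#' @param fold_change_phi Multiplicative client-stability effect
#'   \eqn{\phi \ge 0} relative to wild type.
#' @param gfp_scale,mcherry_scale Channel gain constants, `> 0`.
#' @param noise_cv Coefficient of variation of the multiplicative
#'   per-channel noise, `>= 0`.
#' @param autofluor_g,autofluor_r Additive background means, `>= 0`.
#' @param live_scatter,debris_params Log-normal `meanlog`/`sdlog`
#'   parameters for the live and debris FSC/SSC clusters. Defaults put
#'   the debris median FSC 10x below the live median.
#' @param seed Integer RNG seed; identical configs (including seed)
#'   yield bit-identical samples.
#' @return An object of class `synth_config` (a validated list).
#' @seealso [simulate_sample()], [simulate_panel()]
#' @export
synth_config <- function(n_cells = 20000L,
                         live_fraction = 0.85,
                         expr_mu = log(1000),
                         expr_sigma = 0.8,
                         fold_change_phi = 1,
                         gfp_scale = 1,
                         mcherry_scale = 1,
                         noise_cv = 0.3,
                         autofluor_g = 5,
                         autofluor_r = 5,
                         live_scatter = list(fsc_meanlog = log(1e5),
                                             fsc_sdlog = 0.20,
                                             ssc_meanlog = log(5e4),
                                             ssc_sdlog = 0.25),
                         debris_params = list(fsc_meanlog = log(1e4),
                                              fsc_sdlog = 1.5,
                                              ssc_meanlog = log(5e3),
                                              ssc_sdlog = 1.5),
                         seed = 1L) {
  cfg <- list(
    n_cells = check_scalar(n_cells, "n_cells", lower = 1),
    live_fraction = check_scalar(live_fraction, "live_fraction", 0, 1),
    expr_mu = check_scalar(expr_mu, "expr_mu"),
    expr_sigma = check_scalar(expr_sigma, "expr_sigma", lower = 0),
    fold_change_phi = check_scalar(fold_change_phi, "fold_change_phi",
                                   lower = 0),
    gfp_scale = check_scalar(gfp_scale, "gfp_scale", lower = 0,
                             strict_lower = TRUE),
    mcherry_scale = check_scalar(mcherry_scale, "mcherry_scale", lower = 0,
                                 strict_lower = TRUE),
    noise_cv = check_scalar(noise_cv, "noise_cv", lower = 0),
    autofluor_g = check_scalar(autofluor_g, "autofluor_g", lower = 0),
    autofluor_r = check_scalar(autofluor_r, "autofluor_r", lower = 0),
    live_scatter = check_scatter_params(live_scatter, "live_scatter"),
    debris_params = check_scatter_params(debris_params, "debris_params"),
    seed = as.integer(check_seed(seed))
  )
  if (cfg$n_cells != trunc(cfg$n_cells)) {
    stop("`n_cells` must be an integer count", call. = FALSE)
  }
  cfg$n_cells <- as.integer(cfg$n_cells)
  structure(cfg, class = "synth_config")
}

check_scatter_params <- function(p, name) {
  need <- c("fsc_meanlog", "fsc_sdlog", "ssc_meanlog", "ssc_sdlog")
  if (!is.list(p) || !all(need %in% names(p))) {
    stop(sprintf("`%s` must be a list with fields %s", name,
                 paste(need, collapse = ", ")), call. = FALSE)
  }
  for (f in need) p[[f]] <- check_scalar(p[[f]], paste0(name, "$", f))
  for (f in c("fsc_sdlog", "ssc_sdlog")) {
    if (p[[f]] < 0) stop(sprintf("`%s$%s` must be >= 0", name, f),
                         call. = FALSE)
  }
  p[need]
}

#' Simulate one flow-cytometry sample
#'
#' Draws `n_cells` events under the generative model described in
#' [synth_config()]. All random draws are made for every event in a fixed
#' order (population label, expression, channel noise, live scatter,
#' debris scatter), so two configs sharing a seed consume identical
#' random streams: changing only `fold_change_phi` leaves GFP and scatter
#' bit-identical and rescales live-cell mCherry by the ratio of fold
#' changes — a common-random-numbers construction that makes paired
#' contrasts noise-free.
#'
#' @param config A [synth_config()].
#' @param sample_id Sample name stored on the result.
#' @return An `event_table` (see [event_table()]) with a logical
#'   `live_truth` attribute carrying the ground-truth population labels.
#' @export
simulate_sample <- function(config, sample_id = "synthetic") {
  if (!inherits(config, "synth_config")) {
    stop("`config` must be created by synth_config()", call. = FALSE)
  }
  n <- config$n_cells
  set.seed(config$seed)

  live <- stats::runif(n) < config$live_fraction
  E <- stats::rlnorm(n, config$expr_mu, config$expr_sigma)
  # Unit-mean multiplicative noise: sdlog from the CV, meanlog = -sdlog^2/2.
  sdlog_eps <- sqrt(log1p(config$noise_cv^2))
  eps_g <- stats::rlnorm(n, -sdlog_eps^2 / 2, sdlog_eps)
  eps_r <- stats::rlnorm(n, -sdlog_eps^2 / 2, sdlog_eps)
  ls <- config$live_scatter
  dp <- config$debris_params
  fsc_live <- stats::rlnorm(n, ls$fsc_meanlog, ls$fsc_sdlog)
  ssc_live <- stats::rlnorm(n, ls$ssc_meanlog, ls$ssc_sdlog)
  fsc_deb <- stats::rlnorm(n, dp$fsc_meanlog, dp$fsc_sdlog)
  ssc_deb <- stats::rlnorm(n, dp$ssc_meanlog, dp$ssc_sdlog)

  gfp <- ifelse(live,
                E * config$gfp_scale * eps_g + config$autofluor_g,
                config$autofluor_g * eps_g)
  mch <- ifelse(live,
                E * config$fold_change_phi * config$mcherry_scale * eps_r +
                  config$autofluor_r,
                config$autofluor_r * eps_r)

  tab <- event_table(
    fsc_a = ifelse(live, fsc_live, fsc_deb),
    ssc_a = ifelse(live, ssc_live, ssc_deb),
    gfp = gfp,
    mcherry = mch,
    sample_id = sample_id,
    provenance = sprintf("simulate_sample(seed=%d)", config$seed)
  )
  attr(tab, "live_truth") <- live
  tab
}

#' Simulate a mutant panel with matched wild-type references
#'
#' Generates one sample per row of `panel_spec` and assembles the sample
#' manifest the pipeline consumes. Each sample's RNG stream is keyed by
#' `(sample_id, seed)` via [derive_seed()] unless the row supplies an
#' explicit `seed`, so a panel is reproducible sample-by-sample.
#'
#' @param panel_spec Data frame with columns `sample_id`, `ko_subunit`,
#'   `rescue_variant`, `client`, `is_wt_reference` (logical), `phi`
#'   (fold change), and optionally `seed` (per-sample override) plus any
#'   further [synth_config()] field as a column.
#' @param base_config [synth_config()] supplying every parameter not
#'   overridden per row.
#' @param seed Panel-level base seed.
#' @param dir Optional directory; when given, each sample is written as
#'   TSV there and the manifest `path` column points at the files.
#' @return A list with `tables` (named list of `event_table`s) and
#'   `manifest` (data frame with columns `sample_id`, `path`,
#'   `ko_subunit`, `rescue_variant`, `client`, `is_wt_reference`,
#'   `truth_phi`).
#' @export
simulate_panel <- function(panel_spec, base_config = synth_config(),
                           seed = 1L, dir = NULL) {
  need <- c("sample_id", "ko_subunit", "rescue_variant", "client",
            "is_wt_reference", "phi")
  if (nrow2(panel_spec) == 0L) {
    manifest <- empty_manifest()
    return(list(tables = structure(list(), names = character()),
                manifest = manifest))
  }
  if (!all(need %in% names(panel_spec))) {
    stop("panel_spec is missing columns: ",
         paste(setdiff(need, names(panel_spec)), collapse = ", "),
         call. = FALSE)
  }
  ids <- as.character(panel_spec$sample_id)
  if (anyDuplicated(ids)) {
    stop("duplicate sample ids in panel_spec: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  }
  check_wt_references(panel_spec)
  seed <- check_seed(seed)

  overridable <- setdiff(names(panel_spec),
                         c(need, "seed", "path"))
  tables <- vector("list", nrow(panel_spec))
  names(tables) <- ids
  paths <- rep(NA_character_, nrow(panel_spec))
  for (i in seq_len(nrow(panel_spec))) {
    row <- panel_spec[i, ]
    args <- as.list(base_config)[setdiff(names(base_config), "seed")]
    args$fold_change_phi <- row$phi
    for (f in intersect(overridable, names(formals(synth_config)))) {
      args[[f]] <- row[[f]]
    }
    args$seed <- if ("seed" %in% names(panel_spec) && !is.na(row$seed)) {
      row$seed
    } else {
      derive_seed(ids[i], seed)
    }
    tables[[i]] <- simulate_sample(do.call(synth_config, args), ids[i])
    if (!is.null(dir)) {
      paths[i] <- file.path(dir, paste0(ids[i], ".tsv"))
      write_events(tables[[i]], paths[i], format = "tsv")
    }
  }

  manifest <- data.frame(
    sample_id = ids,
    path = paths,
    ko_subunit = as.character(panel_spec$ko_subunit),
    rescue_variant = as.character(panel_spec$rescue_variant),
    client = as.character(panel_spec$client),
    is_wt_reference = as.logical(panel_spec$is_wt_reference),
    truth_phi = as.numeric(panel_spec$phi),
    stringsAsFactors = FALSE
  )
  list(tables = tables, manifest = manifest)
}

check_wt_references <- function(spec) {
  groups <- split(spec$is_wt_reference,
                  paste(spec$ko_subunit, spec$client, sep = " / "))
  n_wt <- vapply(groups, function(x) sum(as.logical(x)), integer(1))
  bad <- names(n_wt)[n_wt != 1L]
  if (length(bad)) {
    stop("each (ko_subunit, client) group needs exactly one WT reference; ",
         "violated for: ", paste(bad, collapse = "; "), call. = FALSE)
  }
  invisible(TRUE)
}

empty_manifest <- function() {
  data.frame(sample_id = character(), path = character(),
             ko_subunit = character(), rescue_variant = character(),
             client = character(), is_wt_reference = logical(),
             truth_phi = numeric(), stringsAsFactors = FALSE)
}

nrow2 <- function(x) if (is.null(x)) 0L else nrow(as.data.frame(x))
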