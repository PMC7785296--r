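# Shared fixture builders: everything is generated in code at test time.

# A small, fast sample config; overrides pass through to synth_config().
quick_config <- function(n_cells = 2000, seed = 1, ...) {
  synth_config(n_cells = n_cells, seed = seed, ...)
}

# Live-only normalized-ratio machinery used by the statistical tests:
# simulate a pure live sample and return its per-cell ratio object.
live_ratios <- function(phi, n = 2000, seed = 1, noise_cv = 0.3,
                        id = "live") {
  tab <- simulate_sample(synth_config(n_cells = n, live_fraction = 1,
                                      fold_change_phi = phi,
                                      noise_cv = noise_cv, seed = seed),
                         sample_id = id)
  compute_ratios(tab)
}

# A minimal three-client panel spec data frame.
make_panel_spec <- function(clients = c("SQS378-410", "B1AR", "TMEM97"),
                            phis = c(WT = 1, mutA = 0.5),
                            ko = "EMC3") {
  rows <- expand.grid(variant = names(phis), client = clients,
                      stringsAsFactors = FALSE)
  mut_names <- stats::setNames(
    paste0(ko, "_N", 100 + seq_along(phis), "D"), names(phis))
  data.frame(
    sample_id = paste(ko, rows$variant, rows$client, sep = "_"),
    ko_subunit = ko,
    rescue_variant = ifelse(rows$variant == "WT", "WT",
                            unname(mut_names[rows$variant])),
    client = rows$client,
    is_wt_reference = rows$variant == "WT",
    phi = unname(phis[rows$variant]),
    stringsAsFactors = FALSE
  )
}
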