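#' Pipeline configuration
#'
#' Bundles every tunable of the panel pipeline with the assay's standard
#' defaults: gate fraction 0.85, median wild-type normalizer, bootstrap
#' of 1000 iterations of 50 cells, dual one-sided Welch tests at a
#' per-direction cutoff of 0.01, no multiple-testing correction (a
#' fixed per-test cutoff; Benjamini-Hochberg is available via
#' `p_adjust = "BH"`, applied per direction across the panel).
#'
#' @param target_fraction Density-gate retained fraction, `(0, 1]`.
#' @param statistic Wild-type normalizer statistic, `"median"`/`"mean"`.
#' @param B,m Bootstrap iterations and cells per iteration.
#' @param alpha Per-direction significance cutoff.
#' @param test_variant `"welch"`, `"pooled"`, or `"z"`.
#' @param p_adjust `"none"` (default) or a [stats::p.adjust()] method
#'   applied per direction across all mutants before classification.
#' @param seed Base seed; every per-sample stream is derived from it
#'   with [derive_seed()].
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(target_fraction = 0.85,
                            statistic = c("median", "mean"),
                            B = 1000L, m = 50L, alpha = 0.01,
                            test_variant = c("welch", "pooled", "z"),
                            p_adjust = "none",
                            seed = 1L) {
  cfg <- list(
    target_fraction = check_scalar(target_fraction, "target_fraction",
                                   lower = 0, upper = 1,
                                   strict_lower = TRUE),
    statistic = match.arg(statistic),
    B = as.integer(check_scalar(B, "B", lower = 1)),
    m = as.integer(check_scalar(m, "m", lower = 1)),
    alpha = check_scalar(alpha, "alpha", lower = 0, upper = 1),
    test_variant = match.arg(test_variant),
    p_adjust = p_adjust,
    seed = as.integer(check_seed(seed))
  )
  if (!cfg$p_adjust %in% c("none", stats::p.adjust.methods)) {
    stop("unknown p_adjust method: ", cfg$p_adjust, call. = FALSE)
  }
  structure(cfg, class = "pipeline_config")
}

#' Run the full reporter-quantification pipeline over a manifest
#'
#' For every sample: read (or take from `tables`), gate on scatter,
#' compute per-cell mCherry:GFP ratios, normalize to the wild-type
#' reference of the same (knockout background, client) group, bootstrap
#' the mean, and test each mutant against its reference with the dual
#' one-sided test. The whole run is deterministic given the manifest,
#' config, and seed: each sample's bootstrap stream is keyed by
#' `(sample_id, seed)`.
#'
#' A mutant whose event data are identical to its wild-type reference
#' (for example, a reference deliberately re-listed as a mutant row
#' pointing at the same file) is compared against the reference's own
#' bootstrap distribution, which makes the comparison an exact self-null:
#' `t = 0`, both p-values 0.5, category `wt_like`.
#'
#' @param manifest Data frame with columns `sample_id`, `path`,
#'   `ko_subunit`, `rescue_variant`, `client`, `is_wt_reference`
#'   (`truth_phi` optional, synthetic panels only). Exactly one WT
#'   reference per (ko_subunit, client).
#' @param run_config A [pipeline_config()].
#' @param tables Optional named list of in-memory [event_table()]s keyed
#'   by `sample_id`, used instead of reading `path` (synthetic runs).
#' @param format File format for `path` reads.
#' @return An object of class `panel_result`: `calls` (one row per
#'   mutant x client), `category_counts` (per client), `qc` (per
#'   sample), `run_config`.
#' @export
run_pipeline <- function(manifest, run_config = pipeline_config(),
                         tables = NULL, format = c("tsv", "fcs")) {
  format <- match.arg(format)
  if (!inherits(run_config, "pipeline_config")) {
    stop("`run_config` must be a pipeline_config()", call. = FALSE)
  }
  manifest <- validate_manifest(manifest, tables)

  load_table <- function(row) {
    if (!is.null(tables) && row$sample_id %in% names(tables)) {
      tab <- tables[[row$sample_id]]
      if (!inherits(tab, "event_table")) {
        stop("tables[['", row$sample_id, "']] is not an event_table",
             call. = FALSE)
      }
      return(tab)
    }
    read_events(row$path, format = format, sample_id = row$sample_id)
  }

  calls <- list()
  qc <- list()
  groups <- split(seq_len(nrow(manifest)),
                  paste(manifest$ko_subunit, manifest$client, sep = " / "))
  for (grp in groups) {
    rows <- manifest[grp, ]
    wt_row <- rows[rows$is_wt_reference, ][1, ]
    wt_tab <- with_sample_context(wt_row$sample_id, load_table(wt_row))
    wt_gate <- with_sample_context(wt_row$sample_id,
                                   gate_live(wt_tab, run_config$target_fraction))
    wt_raw <- with_sample_context(wt_row$sample_id,
                                  compute_ratios(wt_tab, wt_gate))
    wt_set <- normalize_to_reference(wt_raw, wt_raw, run_config$statistic)
    wt_boot <- bootstrap_means(wt_set, B = run_config$B, m = run_config$m,
                               seed = derive_seed(wt_row$sample_id,
                                                  run_config$seed))
    qc[[wt_row$sample_id]] <- qc_summary(wt_tab, wt_gate)

    for (i in seq_len(nrow(rows))) {
      row <- rows[i, ]
      if (row$is_wt_reference) next
      sid <- row$sample_id
      tab <- with_sample_context(sid, load_table(row))
      if (identical_events(tab, wt_tab)) {
        # byte-identical to the reference: exact self-null on the shared
        # bootstrap stream
        gate <- wt_gate
        boot <- wt_boot
        boot$sample_id <- sid
        qc[[sid]] <- qc_summary(tab, gate)
      } else {
        gate <- with_sample_context(sid,
                                    gate_live(tab, run_config$target_fraction))
        raw <- with_sample_context(sid, compute_ratios(tab, gate))
        mset <- normalize_to_reference(raw, wt_raw, run_config$statistic)
        boot <- bootstrap_means(mset, B = run_config$B, m = run_config$m,
                                seed = derive_seed(sid, run_config$seed))
        qc[[sid]] <- qc_summary(tab, gate)
      }
      call <- dual_one_sided_test(boot, wt_boot, alpha = run_config$alpha,
                                  variant = run_config$test_variant,
                                  client = row$client)
      calls[[length(calls) + 1L]] <- data.frame(
        sample_id = sid,
        ko_subunit = row$ko_subunit,
        rescue_variant = row$rescue_variant,
        client = row$client,
        mu_hat_mut = call$mu_hat_mut,
        mu_hat_wt = call$mu_hat_wt,
        t_stat = call$t_stat,
        df = call$df,
        p_decrease = call$p_decrease,
        p_increase = call$p_increase,
        category = call$category,
        stringsAsFactors = FALSE
      )
    }
  }

  calls <- if (length(calls)) do.call(rbind, calls) else empty_calls()
  rownames(calls) <- NULL
  if (run_config$p_adjust != "none" && nrow(calls)) {
    calls$p_decrease_adj <- stats::p.adjust(calls$p_decrease,
                                            run_config$p_adjust)
    calls$p_increase_adj <- stats::p.adjust(calls$p_increase,
                                            run_config$p_adjust)
    calls$category <- mapply(function(pd, pi_) {
      if (pd < run_config$alpha) "decreased"
      else if (pi_ < run_config$alpha) "increased"
      else "wt_like"
    }, calls$p_decrease_adj, calls$p_increase_adj)
  }

  structure(list(
    calls = calls,
    category_counts = count_categories(calls),
    qc = do.call(rbind, c(qc, list(make.row.names = FALSE))),
    run_config = run_config
  ), class = "panel_result")
}

with_sample_context <- function(sample_id, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("sample '%s': %s", sample_id, conditionMessage(e)),
         call. = FALSE)
  })
}

identical_events <- function(a, b) {
  nrow(a) == nrow(b) &&
    identical(a$fsc_a, b$fsc_a) && identical(a$ssc_a, b$ssc_a) &&
    identical(a$gfp, b$gfp) && identical(a$mcherry, b$mcherry)
}

empty_calls <- function() {
  data.frame(sample_id = character(), ko_subunit = character(),
             rescue_variant = character(), client = character(),
             mu_hat_mut = numeric(), mu_hat_wt = numeric(),
             t_stat = numeric(), df = numeric(),
             p_decrease = numeric(), p_increase = numeric(),
             category = character(), stringsAsFactors = FALSE)
}

count_categories <- function(calls) {
  cats <- c("decreased", "wt_like", "increased")
  if (!nrow(calls)) {
    return(data.frame(client = character(),
                      decreased = integer(), wt_like = integer(),
                      increased = integer(), stringsAsFactors = FALSE))
  }
  out <- lapply(split(calls, calls$client), function(d) {
    n <- table(factor(d$category, levels = cats))
    data.frame(client = d$client[1], decreased = as.integer(n["decreased"]),
               wt_like = as.integer(n["wt_like"]),
               increased = as.integer(n["increased"]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$client), , drop = FALSE]
}

validate_manifest <- function(manifest, tables = NULL) {
  need <- c("sample_id", "ko_subunit", "rescue_variant", "client",
            "is_wt_reference")
  if (!all(need %in% names(manifest))) {
    stop("manifest is missing columns: ",
         paste(setdiff(need, names(manifest)), collapse = ", "),
         call. = FALSE)
  }
  manifest$sample_id <- as.character(manifest$sample_id)
  manifest$is_wt_reference <- as.logical(manifest$is_wt_reference)
  if (anyDuplicated(manifest$sample_id)) {
    stop("duplicate sample ids in manifest", call. = FALSE)
  }
  check_wt_references(manifest)
  from_file <- if (is.null(tables)) rep(TRUE, nrow(manifest))
               else !(manifest$sample_id %in% names(tables))
  if (any(from_file)) {
    if (!"path" %in% names(manifest)) {
      stop("manifest needs a `path` column for samples without in-memory ",
           "tables", call. = FALSE)
    }
    missing <- from_file & (is.na(manifest$path) | !file.exists(manifest$path))
    if (any(missing)) {
      stop("event files not found for: ",
           paste(manifest$sample_id[missing], collapse = ", "),
           call. = FALSE)
    }
  }
  manifest
}

#' @export
print.panel_result <- function(x, ...) {
  cat(sprintf("<panel_result> %d calls across %d client(s)\n",
              nrow(x$calls), length(unique(x$calls$client))))
  print(x$category_counts)
  invisible(x)
}

#' Assemble the mutant x client phenotype matrix
#'
#' Pivots the per-call table into one row per mutant (rescue variant)
#' and one column per client, each cell holding the phenotype category.
#' Combinations absent from the calls are marked `"missing"` explicitly.
#'
#' @param calls The `calls` data frame from [run_pipeline()] (or a
#'   `panel_result`).
#' @param clients Column order; defaults to the clients present.
#' @return Data frame, first column `rescue_variant`, one column per
#'   client.
#' @export
assemble_matrix <- function(calls, clients = NULL) {
  if (inherits(calls, "panel_result")) calls <- calls$calls
  if (!nrow(calls)) stop("no calls to assemble", call. = FALSE)
  if (anyDuplicated(calls[, c("rescue_variant", "client")])) {
    dup <- calls[duplicated(calls[, c("rescue_variant", "client")]), ]
    stop("duplicate (mutant, client) calls, e.g. ",
         dup$rescue_variant[1], " / ", dup$client[1], call. = FALSE)
  }
  if (is.null(clients)) clients <- sort(unique(calls$client))
  mutants <- unique(calls$rescue_variant)
  out <- data.frame(rescue_variant = mutants, stringsAsFactors = FALSE)
  for (cl in clients) {
    sub <- calls[calls$client == cl, ]
    out[[cl]] <- sub$category[match(mutants, sub$rescue_variant)]
    out[[cl]][is.na(out[[cl]])] <- "missing"
  }
  out
}

#' Parse a rescue-variant mutation string
#'
#' Mutation strings name the subunit and one or more single-residue
#' substitutions joined by `+`, e.g. `"EMC3_N114D+N117D"`: wild-type
#' residue letter, 1-based position, mutant letter. `"WT"` denotes the
#' unmutated rescue and parses to zero substitutions.
#'
#' @param s Mutation string.
#' @return List with `subunit` (character, `NA` for WT) and
#'   `substitutions` (data frame `wt_aa`, `position`, `mut_aa`).
#' @export
parse_mutation <- function(s) {
  if (length(s) != 1L || !is.character(s) || is.na(s)) {
    stop("mutation string must be a single character value", call. = FALSE)
  }
  if (identical(toupper(s), "WT")) {
    return(list(subunit = NA_character_,
                substitutions = data.frame(wt_aa = character(),
                                           position = integer(),
                                           mut_aa = character(),
                                           stringsAsFactors = FALSE)))
  }
  m <- regmatches(s, regexec("^([A-Za-z0-9]+)_(.+)$", s))[[1]]
  if (length(m) != 3L) {
    stop("cannot parse mutation string '", s,
         "': expected SUBUNIT_<substitutions>", call. = FALSE)
  }
  subunit <- m[2]
  toks <- strsplit(m[3], "+", fixed = TRUE)[[1]]
  subs <- lapply(toks, function(tok) {
    mm <- regmatches(tok, regexec("^([A-Z])([0-9]+)([A-Z])$", tok))[[1]]
    if (length(mm) != 4L) {
      stop("cannot parse substitution token '", tok, "' in '", s, "'",
           call. = FALSE)
    }
    pos <- as.integer(mm[3])
    if (pos < 1L) stop("residue positions are 1-based in '", s, "'",
                       call. = FALSE)
    data.frame(wt_aa = mm[2], position = pos, mut_aa = mm[4],
               stringsAsFactors = FALSE)
  })
  list(subunit = subunit, substitutions = do.call(rbind, subs))
}

#' Export per-residue structure-annotation attributes for one client
#'
#' Writes a viewer-agnostic plain-text attribute table mapping each
#' mutated residue to its phenotype category for the chosen client —
#' one record per residue with the subunit (chain), 1-based residue
#' number, category label, and the conventional display colour
#' ([category_colors()]). Wild-type rescue rows contribute no residues.
#' Residue numbering is taken verbatim from the mutation strings.
#'
#' @param calls `calls` data frame from [run_pipeline()] (or a
#'   `panel_result`).
#' @param client Client to export.
#' @param path Optional output file; when `NULL` nothing is written.
#' @param ref_seqs Optional named character vector of subunit sequences;
#'   when given, each substitution's wild-type letter is checked against
#'   the sequence and a mismatch is an error.
#' @return The attribute data frame (`subunit`, `residue`, `category`,
#'   `color`), invisibly when `path` is given.
#' @export
export_residue_attributes <- function(calls, client, path = NULL,
                                      ref_seqs = NULL) {
  if (inherits(calls, "panel_result")) calls <- calls$calls
  sub <- calls[calls$client == client, , drop = FALSE]
  if (!nrow(sub)) stop("no calls for client '", client, "'", call. = FALSE)
  cols <- category_colors()
  rows <- list()
  for (i in seq_len(nrow(sub))) {
    parsed <- parse_mutation(sub$rescue_variant[i])
    if (!nrow(parsed$substitutions)) next
    if (!is.null(ref_seqs) && parsed$subunit %in% names(ref_seqs)) {
      seq_chars <- strsplit(ref_seqs[[parsed$subunit]], "")[[1]]
      for (j in seq_len(nrow(parsed$substitutions))) {
        pos <- parsed$substitutions$position[j]
        want <- parsed$substitutions$wt_aa[j]
        if (pos > length(seq_chars) || seq_chars[pos] != want) {
          stop(sprintf(
            "substitution %s%d in '%s' does not match the %s reference sequence",
            want, pos, sub$rescue_variant[i], parsed$subunit), call. = FALSE)
        }
      }
    }
    rows[[length(rows) + 1L]] <- data.frame(
      subunit = parsed$subunit,
      residue = parsed$substitutions$position,
      category = sub$category[i],
      color = unname(cols[sub$category[i]]),
      stringsAsFactors = FALSE
    )
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(subunit = character(), residue = integer(),
                         category = character(), color = character(),
                         stringsAsFactors = FALSE)
  rownames(out) <- NULL
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(out))
  }
  out
}

#' Export a panel result as delimited text
#'
#' Writes `calls.tsv`, `category_counts.tsv`, `qc.tsv`, the phenotype
#' matrix `matrix.tsv`, and the resolved configuration `config.json`
#' into `dir`. Output is plain text with fixed formatting, so two runs
#' from the same manifest, config and seed produce byte-identical files.
#'
#' @param result A [run_pipeline()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
export_panel <- function(result, dir) {
  if (!inherits(result, "panel_result")) {
    stop("`result` must be a panel_result", call. = FALSE)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(d, f) {
    utils::write.table(format(d, digits = 15, trim = TRUE, scientific = FALSE),
                       file.path(dir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  wr(result$calls, "calls.tsv")
  wr(result$category_counts, "category_counts.tsv")
  wr(result$qc, "qc.tsv")
  if (nrow(result$calls)) wr(assemble_matrix(result$calls), "matrix.tsv")
  jsonlite::write_json(unclass(result$run_config),
                       file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
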