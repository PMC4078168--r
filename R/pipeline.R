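#' Read/write long-format trait tables
#'
#' Trait CSVs have header `species,trait_name,state`; one row per species
#' per trait. `read_trait_table` returns a named list (one element per
#' trait) of named state vectors.
#'
#' @param file Path to a CSV file.
#' @return Named list of named character vectors.
#' @name trait-io
#' @export
read_trait_table <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("species", "trait_name", "state")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stopf("trait CSV missing column(s): %s", paste(miss, collapse = ", "))
  lapply(split(df, df$trait_name), function(d) {
    if (anyDuplicated(d$species))
      stopf("duplicate species in trait '%s'", d$trait_name[1])
    stats::setNames(d$state, trimws(d$species))
  })
}

#' @rdname trait-io
#' @param traits Named list of named state vectors.
#' @export
write_trait_table <- function(traits, file) {
  rows <- lapply(names(traits), function(tn)
    data.frame(species = names(traits[[tn]]), trait_name = tn,
               state = as.character(unlist(traits[[tn]]))))
  utils::write.csv(do.call(rbind, rows), file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Descriptive treatment differences in diversity
#'
#' Percent reduction in mean species richness, Shannon diversity and MPD in
#' browsed (control) relative to unbrowsed (exclosure) plots,
#' \eqn{100 (\bar x_{excl} - \bar x_{ctl}) / \bar x_{excl}}, with means
#' taken over all plot-years of each treatment. A descriptive summary:
#' formal mixed-model inference on the treatment effect is deliberately left
#' to external tools (the per-plot table is tidy for that purpose).
#'
#' @param diversity A [diversity_by_plot()] table (with or without `mpd`).
#' @return Data frame with columns `metric`, `mean_exclosure`,
#'   `mean_control`, `pct_reduction` (`NA` with a warning when the exclosure
#'   mean is zero).
#' @export
summarize_treatment_differences <- function(diversity) {
  metrics <- intersect(c("richness", "shannon", "mpd"), names(diversity))
  if (!all(c("exclosure", "control") %in% diversity$treatment))
    stopf("both treatments must be present")
  out <- lapply(metrics, function(m) {
    me <- mean(diversity[[m]][diversity$treatment == "exclosure"], na.rm = TRUE)
    mc <- mean(diversity[[m]][diversity$treatment == "control"], na.rm = TRUE)
    pct <- if (isTRUE(me == 0)) {
      warnf("exclosure mean of %s is zero; percent reduction undefined", m)
      NA_real_
    } else 100 * (me - mc) / me
    data.frame(metric = m, mean_exclosure = me, mean_control = mc,
               pct_reduction = pct)
  })
  do.call(rbind, out)
}

.default_synthetic <- function() {
  list(n_species = 50L, birth_rate = 1, years = c(2006, 2008:2012),
       n_sites = 4L, occupancy = 0.4, cover_meanlog = 0.5, cover_sdlog = 0.8,
       prevalence = 25L, sigma2 = 1, mk_states = 6L, mk_rate = 0.15,
       trait_model = "threshold_bm",
       retention = list(abiotic = 1.0, biotic = 0.25))
}

.pipeline_inputs <- function(cfg, seed) {
  if (!is.null(cfg$synthetic)) {
    syn <- utils::modifyList(.default_synthetic(), cfg$synthetic)
    if (is.null(cfg$synthetic$prevalence))
      syn$prevalence <- max(1L, round(syn$n_species / 2))
    tree <- sim_yule_tree(syn$n_species, syn$birth_rate,
                          seed = derive_seed(seed, "tree"))
    pollination <- if (identical(syn$trait_model, "clade")) {
      # taxonomically clustered tolerance: the clade whose size is nearest
      # the target number of tolerant species is abiotically pollinated
      parts <- ape::prop.part(tree)
      sizes <- lengths(parts)
      n_tol <- syn$n_species - syn$prevalence
      ok <- which(sizes < syn$n_species)
      pick <- ok[which.min(abs(sizes[ok] - n_tol))]
      clade <- tree$tip.label[parts[[pick]]]
      stats::setNames(ifelse(tree$tip.label %in% clade, "abiotic", "biotic"),
                      tree$tip.label)
    } else {
      liab <- sim_brownian_trait(tree, syn$sigma2,
                                 seed = derive_seed(seed, "liability"))
      bin <- threshold_binarize(liab, syn$prevalence,
                                seed = derive_seed(seed, "threshold"))
      stats::setNames(ifelse(bin == 1, "biotic", "abiotic"), names(bin))
    }
    browse_states <- c("woody", "broadleaf_forb", "fern",
                       "grass", "sedge", "lycopod")
    mk <- sim_mk_trait(tree, n_states = syn$mk_states, rate = syn$mk_rate,
                       seed = derive_seed(seed, "browse_type"))
    browse <- stats::setNames(browse_states[mk], names(mk))
    sim <- sim_browse_panel(
      tree, trait = pollination, retention = syn$retention,
      years = syn$years, n_sites = syn$n_sites, occupancy = syn$occupancy,
      cover_meanlog = syn$cover_meanlog, cover_sdlog = syn$cover_sdlog,
      seed = derive_seed(seed, "panel"))
    list(tree = tree, panel = sim$panel, records = sim$records,
         traits = list(pollination_mode = pollination, browse_type = browse),
         binary_traits = "pollination_mode", multistate_traits = "browse_type",
         synthetic = syn)
  } else {
    inp <- cfg$inputs
    if (is.null(inp$tree)) stopf("config must name a tree file")
    tree <- read_newick(file = inp$tree)
    panel <- if (!is.null(inp$transects)) {
      compute_cover(read_transect_records(inp$transects))
    } else if (!is.null(inp$cover)) {
      read_cover_panel(inp$cover)
    } else stopf("config must name a `transects` or `cover` file")
    traits <- if (!is.null(inp$traits)) read_trait_table(inp$traits) else list()
    want <- c(cfg$binary_traits, cfg$multistate_traits)
    absent <- setdiff(want, names(traits))
    if (length(absent))
      stopf("trait(s) requested but not in trait table: %s",
            paste(absent, collapse = ", "))
    list(tree = tree, panel = panel, records = NULL, traits = traits,
         binary_traits = cfg$binary_traits %||%
           character(0),
         multistate_traits = cfg$multistate_traits %||% character(0),
         synthetic = NULL)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.signal_tests <- function(tree, traits, binary, multistate, n_perm, seed) {
  rows <- list()
  for (tn in binary) {
    tr_states <- traits[[tn]]
    use_tree <- tree
    dropped <- setdiff(tree$tip.label, names(tr_states))
    if (length(dropped)) {
      warnf("trait '%s': pruning %d tip(s) without a state", tn, length(dropped))
      use_tree <- prune_tree(tree, intersect(tree$tip.label, names(tr_states)))
    }
    res <- d_statistic(use_tree, tr_states, n_perm = n_perm,
                       seed = derive_seed(seed, paste0("d/", tn)))
    rows[[length(rows) + 1L]] <- data.frame(
      trait = tn, test = "d_statistic", statistic = res$D,
      observed = res$d_obs, null_mean_random = res$mean_d_random,
      null_mean_brownian = res$mean_d_brownian, null_ci_lo = NA_real_,
      null_ci_hi = NA_real_, p_random = res$p_random,
      p_brownian = res$p_brownian, p_value = res$p_random,
      n_perm = res$n_perm, seed = res$seed)
  }
  for (tn in multistate) {
    tr_states <- traits[[tn]]
    use_tree <- tree
    dropped <- setdiff(tree$tip.label, names(tr_states))
    if (length(dropped)) {
      warnf("trait '%s': pruning %d tip(s) without a state", tn, length(dropped))
      use_tree <- prune_tree(tree, intersect(tree$tip.label, names(tr_states)))
    }
    res <- parsimony_signal_test(use_tree, tr_states, n_perm = n_perm,
                                 seed = derive_seed(seed, paste0("pars/", tn)))
    rows[[length(rows) + 1L]] <- data.frame(
      trait = tn, test = "parsimony", statistic = res$observed_steps,
      observed = res$observed_steps, null_mean_random = res$null_mean,
      null_mean_brownian = NA_real_, null_ci_lo = res$null_ci[1],
      null_ci_hi = res$null_ci[2], p_random = res$p_value,
      p_brownian = NA_real_, p_value = res$p_value,
      n_perm = res$n_perm, seed = res$seed)
  }
  if (length(rows)) do.call(rbind, rows) else NULL
}

#' Run the full browsing-filter analysis
#'
#' One-call reproduction of the analysis chain on real or synthetic inputs:
#' transect records (or cover values) to percent cover; per-plot species
#' richness, Shannon diversity and MPD; treatment-pooled NRI by year;
#' phylogenetic-signal tests for configured traits; the rarity-filtered
#' mean-DBSI table; and descriptive treatment differences. All permutation
#' seeds are derived from the single master seed, so a rerun with the same
#' config is bit-identical.
#'
#' The config is a list (or path to a YAML file) with entries:
#' \describe{
#'   \item{seed}{master integer seed (default 1).}
#'   \item{n_perm}{permutations for NRI and signal tests (default 999).}
#'   \item{species_policy}{`"error"` (default) or `"drop"` for panel species
#'     absent from the tree.}
#'   \item{inputs}{list with `tree` (Newick), `transects` or `cover` (CSV),
#'     optional `traits` (CSV).}
#'   \item{binary_traits, multistate_traits}{trait names to test.}
#'   \item{synthetic}{instead of `inputs`: overrides for the synthetic
#'     scenario (`n_species`, `birth_rate`, `years`, `n_sites`, `occupancy`,
#'     `cover_meanlog`, `cover_sdlog`, `prevalence`, `sigma2`, `mk_states`,
#'     `mk_rate`, `retention`, and `trait_model`: `"threshold_bm"` for a
#'     Brownian-threshold pollination mode or `"clade"` for taxonomically
#'     clustered tolerance).}
#' }
#'
#' @param config List or path to a YAML config file.
#' @param out_dir Optional output directory; when given, writes
#'   `diversity.csv`, `nri.csv`, `signal.csv`, `dbsi.csv`,
#'   `treatment_summary.csv`, `report.json` and, for synthetic runs,
#'   the generated `tree.nwk`, `transect_records.csv` and `traits.csv`.
#' @return The report as a list (invisibly when `out_dir` is given).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  seed <- as.integer(cfg$seed %||% 1L)
  n_perm <- as.integer(cfg$n_perm %||% 999L)
  inputs <- .pipeline_inputs(cfg, seed)
  tree <- inputs$tree
  panel <- inputs$panel

  off_tree <- setdiff(unique(panel$species), tree$tip.label)
  if (length(off_tree)) {
    policy <- cfg$species_policy %||% "error"
    if (policy == "drop") {
      warnf("dropping %d species absent from tree: %s", length(off_tree),
            paste(off_tree, collapse = ", "))
      panel <- cover_panel(panel[!panel$species %in% off_tree, ])
    } else {
      stopf("species present in cover but absent from tree: %s",
            paste(off_tree, collapse = ", "))
    }
  }

  diversity <- diversity_by_plot(panel, tree)
  nri_tab <- nri_by_treatment_year(panel, tree, n_perm = n_perm, seed = seed)
  signal <- .signal_tests(tree, inputs$traits, inputs$binary_traits,
                          inputs$multistate_traits, n_perm, seed)
  dbsi_tab <- mean_dbsi(panel)
  summary_tab <- summarize_treatment_differences(diversity)

  report <- list(
    meta = list(package = "phylobrowse",
                version = as.character(utils::packageVersion("phylobrowse")),
                seed = seed, n_perm = n_perm,
                n_species_pool = length(tree$tip.label),
                synthetic = !is.null(inputs$synthetic)),
    config = cfg,
    treatment_summary = summary_tab,
    diversity = diversity,
    nri = nri_tab,
    signal = signal,
    dbsi = dbsi_tab
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_cover_panel(panel, file.path(out_dir, "cover.csv"))
    utils::write.csv(diversity, file.path(out_dir, "diversity.csv"),
                     row.names = FALSE)
    utils::write.csv(nri_tab, file.path(out_dir, "nri.csv"), row.names = FALSE)
    if (!is.null(signal))
      utils::write.csv(signal, file.path(out_dir, "signal.csv"),
                       row.names = FALSE)
    utils::write.csv(dbsi_tab, file.path(out_dir, "dbsi.csv"),
                     row.names = FALSE)
    utils::write.csv(summary_tab, file.path(out_dir, "treatment_summary.csv"),
                     row.names = FALSE)
    if (!is.null(inputs$synthetic)) {
      write_newick(tree, file.path(out_dir, "tree.nwk"))
      write_transect_records(inputs$records,
                             file.path(out_dir, "transect_records.csv"))
      write_trait_table(inputs$traits, file.path(out_dir, "traits.csv"))
    }
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "rows", na = "null")
    return(invisible(report))
  }
  report
}
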