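# End-to-end orchestration: observables -> contacts -> kinetics ->
# transition state / Phi -> CS/IF, with a machine-readable summary.

#' Build and validate a pipeline run configuration
#'
#' Inputs are either file paths (`reference_pdb`, plus `bound_ensemble` /
#' `apo_ensemble` as multi-model PDB or coordinate tables) or
#' `synthetic = TRUE`, in which case the seeded generators supply every
#' stage's input. Thresholds default to the standard analysis constants:
#' 6.5 A contacts, 11 A electrostatics, 0.5 A bins to 50 A, 10 A local
#' cutoff, 60% stable-contact population, P < 0.1.
#'
#' @param synthetic use the synthetic generators instead of files.
#' @param mechanism planted mechanism for synthetic runs.
#' @param reference_pdb,bound_ensemble,apo_ensemble input paths (ignored
#'   when `synthetic`).
#' @param chain analysed chain label (`NULL`: first chain).
#' @param seed integer seed.
#' @param out_dir output directory (created if needed).
#' @param contact_cutoff,electrostatic_cutoff,bin_width,max_dist,local_cutoff,stable_population,p_threshold
#'   analysis thresholds (Angstrom / fractions).
#' @param n_bound,n_apo frames sampled for the CS/IF stage.
#' @param stride frame stride for the RMSD matrix.
#' @param jump_factor segmentation jump threshold (SDs).
#' @return validated config list of class `run_config`.
#' @export
run_config <- function(synthetic = TRUE, mechanism = "mixed",
                       reference_pdb = NULL, bound_ensemble = NULL,
                       apo_ensemble = NULL, chain = NULL,
                       seed = 1L, out_dir = tempfile("idpmech_run_"),
                       contact_cutoff = 6.5, electrostatic_cutoff = 11,
                       bin_width = 0.5, max_dist = 50, local_cutoff = 10,
                       stable_population = 0.6, p_threshold = 0.1,
                       n_bound = 10L, n_apo = 10L, stride = 1L,
                       jump_factor = 2) {
  cfg <- structure(as.list(environment()), class = "run_config")
  for (th in c("contact_cutoff", "electrostatic_cutoff", "bin_width",
               "max_dist", "local_cutoff", "stable_population",
               "p_threshold"))
    if (cfg[[th]] <= 0) stop("threshold ", th, " must be positive")
  if (!cfg$synthetic) {
    for (f in c("reference_pdb", "bound_ensemble", "apo_ensemble")) {
      if (is.null(cfg[[f]]))
        stop("config field ", f, " is required for file-based runs")
      if (!file.exists(cfg[[f]]))
        stop("config field ", f, ": file not found: ", cfg[[f]])
    }
  }
  cfg
}

.read_ensemble_file <- function(path, label) {
  if (grepl("\\.(pdb|ent)$", path, ignore.case = TRUE))
    read_pdb(path, label = label)
  else
    read_coord_table(path, label = label)
}

.stage <- function(name, expr) {
  t0 <- proc.time()[["elapsed"]]
  out <- tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
  message(sprintf("[idpmech] stage %-12s %.1fs", name,
                  proc.time()[["elapsed"]] - t0))
  out
}

#' Run the full analysis pipeline
#'
#' Executes every stage on the configured inputs, writes TSV outputs and
#' a JSON summary under `config$out_dir`, and returns the summary.
#' Identical config and inputs give an identical summary.
#'
#' @param config a [run_config()].
#' @return the summary list, invisibly.
#' @export
run_all <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  spec <- synthetic_spec(seed = config$seed)

  inputs <- .stage("inputs", {
    if (config$synthetic) {
      toy <- build_toy_complex(spec)
      csif_in <- sample_csif_ensembles(spec, config$mechanism, toy)
      unf <- sample_unfolding_trajectory(spec)
      clus <- sample_clustered_trajectory(spec, toy)
      list(system = toy$system, native = toy$native,
           bound = csif_in$bound, apo = csif_in$apo,
           chain = csif_in$chain, unfolding = unf,
           unfolding_native = attr(unf, "native"), high_t = clus$ensemble)
    } else {
      ref <- read_pdb(config$reference_pdb)
      bound <- .read_ensemble_file(config$bound_ensemble, "bound")
      apo <- .read_ensemble_file(config$apo_ensemble, "apo")
      chain <- if (is.null(config$chain)) ref$system$chains[1L]
               else config$chain
      list(system = ref$system, native = native_contacts(ref$system),
           bound = bound$ensemble, apo = apo$ensemble, chain = chain,
           unfolding = bound$ensemble,
           unfolding_native = native_contacts(bound$ensemble$system),
           high_t = bound$ensemble)
    }
  })

  obs <- .stage("observables", {
    rmsf_b <- ca_rmsf(inputs$bound)
    rmsf_a <- ca_rmsf(inputs$apo)
    hel <- helical_content(inputs$bound)
    fel <- suppressWarnings(free_energy_landscape(inputs$bound))
    utils::write.table(rmsf_b, file.path(config$out_dir, "rmsf_bound.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(rmsf_a, file.path(config$out_dir, "rmsf_apo.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_landscape_xyz(fel, file.path(config$out_dir, "landscape_bound.tsv"))
    list(rmsf_bound = rmsf_b, rmsf_apo = rmsf_a, helicity = hel,
         landscape = fel)
  })

  cont <- .stage("contacts", {
    nat <- inputs$native
    pop <- contact_population(inputs$bound, nat,
                              cutoff = config$contact_cutoff)
    tab <- nat; tab$population <- pop
    write_contact_table(tab, file.path(config$out_dir, "contacts.tsv"))
    list(native = nat, populations = pop,
         n_stable = sum(pop > config$stable_population))
  })

  kin <- .stage("kinetics", {
    qs <- q_series(inputs$unfolding, inputs$unfolding_native)
    channel <- if (qs$n_native_binding > 0L) "qb" else "qf"
    q <- qs[[channel]]
    # fit over the leading window where q stays positive
    last_ok <- max(which(cumsum(q <= 0) == 0), 5L)
    window <- c(qs$times[1L], qs$times[last_ok])
    fit <- fit_first_order(qs, channel, window)
    utils::write.table(as.data.frame(qs),
                       file.path(config$out_dir, "q_series.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(series = qs, fit = fit, channel = channel)
  })

  ts <- .stage("transition_state", {
    rm_ <- rmsd_matrix(inputs$high_t, stride = config$stride)
    proj <- sammon_map(rm_, seed = config$seed)
    seg <- segment_by_time(proj, jump_factor = config$jump_factor)
    phi <- NULL
    if (length(seg$barrier_times) >= 1L) {
      tse <- ts_ensemble(inputs$high_t, seg,
                         half_window_ps = 2 * diff(inputs$high_t$times[1:2]))
      n <- n_frames(inputs$high_t)
      unfolded <- ensemble(inputs$high_t$system,
                           inputs$high_t$coords[(n - max(4L, n %/% 5) + 1L):n, , ,
                                                drop = FALSE],
                           times = inputs$high_t$times[(n - max(4L, n %/% 5) + 1L):n],
                           label = "unfolded")
      folded <- inputs$bound
      phi <- phi_values(tse, folded, unfolded, inputs$native)
      utils::write.table(as.data.frame(phi),
                         file.path(config$out_dir, "phi_profile.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    proj_df <- data.frame(point = seq_len(nrow(proj$points)),
                          time_ps = proj$times %||% seq_len(nrow(proj$points)),
                          x = proj$points[, 1L], y = proj$points[, 2L])
    utils::write.table(proj_df, file.path(config$out_dir, "projection.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(projection = proj, segmentation = seg, phi = phi)
  })

  cs <- .stage("csif", {
    res <- csif_analysis(inputs$bound, inputs$apo, inputs$chain,
                         n_bound = config$n_bound, n_apo = config$n_apo,
                         local_cutoff = config$local_cutoff,
                         bin_width = config$bin_width,
                         max_dist = config$max_dist,
                         p_threshold = config$p_threshold)
    write_csif_tables(res,
                      profile_path = file.path(config$out_dir, "csif_profile.tsv"),
                      delta_path = file.path(config$out_dir, "csif_delta.tsv"))
    res
  })

  summary <- list(
    seed = config$seed,
    chain = inputs$chain,
    n_native_tertiary = attr(cont$native, "n_native_tertiary"),
    n_native_binding = attr(cont$native, "n_native_binding"),
    n_stable_contacts = cont$n_stable,
    helicity = round(obs$helicity, 6),
    kinetics = list(channel = kin$channel,
                    rate_per_ps = round(kin$fit$rate, 8),
                    half_time_ps = round(kin$fit$half_time, 4),
                    se_half_time_ps = round(kin$fit$se_half_time, 4),
                    r_squared = round(kin$fit$r_squared, 6)),
    n_segments = nrow(ts$segmentation$segments),
    barrier_times_ps = round(ts$segmentation$barrier_times, 4),
    sammon_stress = signif(ts$projection$stress, 8),
    mean_phi = if (!is.null(ts$phi))
      round(mean(ts$phi$profile$phi, na.rm = TRUE), 6) else NA,
    delta_global = round(cs$delta_global$delta, 6),
    delta_local = round(cs$delta_local$delta, 6),
    verdict = cs$verdict)
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(summary = summary, observables = obs, contacts = cont,
                 kinetics = kin, transition_state = ts, csif = cs))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
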