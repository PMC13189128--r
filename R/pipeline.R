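## Stage orchestration: simulate -> classify -> the six analysis stages,
## with one config, derived seeds, and a machine-readable results bundle.

PIPELINE_STAGES <- c("simulate", "classify", "state_space", "subspace",
                     "geometry", "encoding", "rsa", "efficiency")

#' Pipeline configuration
#'
#' @param sim A [sim_config()] (or a path to a session container written
#'   by [write_session()]).
#' @param stages Character vector of stages to run, in dependency order;
#'   `classify` requires `simulate` (or a session path), and every
#'   analysis stage requires `classify`.
#' @param seed Master seed; stage-level seeds are derived from it.
#' @param n_perm Permutations for shuffle tests (state space, RSA).
#' @param out_dir Optional directory for JSON/CSV stage outputs.
#' @return List of class `"pipeline_config"`.
#' @export
pipeline_config <- function(sim = sim_config(), stages = PIPELINE_STAGES,
                            seed = 1L, n_perm = 1000, out_dir = NULL) {
  stopifnot(all(stages %in% PIPELINE_STAGES))
  structure(list(sim = sim, stages = stages, seed = seed, n_perm = n_perm,
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the analysis pipeline
#'
#' Executes the enabled stages in dependency order and returns a results
#' bundle containing every stage report, the full configuration, a log,
#' and the package version. Re-running with the same configuration
#' reproduces all stochastic stages exactly (seeds are derived from the
#' master seed per stage).
#'
#' @param config A [pipeline_config()].
#' @return List of class `"pipeline_result"`: `stages` (named reports),
#'   `config`, `log`, `version`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  logline <- character(0)
  note <- function(...) {
    msg <- sprintf(...)
    logline <<- c(logline, paste0(format(Sys.time(), "%H:%M:%S "), msg))
    message(msg)
  }
  stages <- config$stages
  need <- function(st, dep) {
    if (st %in% stages && !dep %in% c(stages, names(out)))
      stop("stage '", st, "' requires stage '", dep, "'", call. = FALSE)
  }
  out <- list()
  for (st in setdiff(stages, "simulate")) need(st, "simulate")
  for (st in setdiff(stages, c("simulate", "classify"))) need(st, "classify")

  if ("simulate" %in% stages) {
    note("simulate: seed %d", config$sim$seed)
    if (is.character(config$sim)) {
      s <- read_session(config$sim)
    } else s <- simulate_session(config$sim)
    out$simulate <- list(session_id = s$session_id,
                         n_units = length(s$units),
                         n_trials = length(s$trials))
  }
  if ("classify" %in% stages) {
    s <- classify_units(s)
    tab <- unit_label_table(s)
    note("classify: %d category-selective, %d attention-selective of %d units",
         sum(tab$category_class %in% c("face_selective", "house_selective")),
         sum(tab$attention_selective, na.rm = TRUE), nrow(tab))
    out$classify <- list(labels = tab)
  }
  foveal <- function() {
    tab <- out$classify$labels
    tab$rf_class %in% c("focal_foveal", "broad_foveal")
  }
  if ("state_space" %in% stages) {
    res <- list()
    for (ep in c("cue", "delay", "search")) {
      cond <- if (ep == "search") "attention" else "category"
      ps <- build_psth_matrix(s, foveal(), epoch = ep, conditions = cond)
      tst <- trajectory_separation_test(ps, n_perm = config$n_perm,
                                        seed = mix_seed(config$seed, "traj", ep))
      res[[ep]] <- list(conditions = cond,
                        sig_bins = sum(tst$significant),
                        n_bins = length(tst$significant),
                        distance = tst$distance, p_fdr = tst$p_fdr)
      note("state_space %s (%s): %d/%d significant bins", ep, cond,
           sum(tst$significant), length(tst$significant))
    }
    out$state_space <- res
  }
  if ("subspace" %in% stages) {
    cp <- build_condition_points(s, foveal(), subspace = "attention")
    lab <- rep(cp$labels$attention, times = length(cp$times))
    acc_par <- classify_component(cp$decomposed, lab, "parallel")
    acc_ort <- classify_component(cp$decomposed, lab, "orthogonal")
    note("subspace: attention accuracy parallel %.2f orthogonal %.2f",
         acc_par$accuracy, acc_ort$accuracy)
    out$subspace <- list(tau = cp$tau,
                         accuracy_parallel = acc_par$accuracy,
                         accuracy_orthogonal = acc_ort$accuracy,
                         n_stimuli = length(cp$stimuli))
  }
  if ("geometry" %in% stages) {
    cc <- context_comparison(s, foveal(), split = "refixation")
    # hyperplane angle on foveal fixation responses, 0-255 ms
    fixtab <- fixation_table(s)
    units <- s$units[foveal()]
    R <- vapply(units, function(u)
      unit_fixation_responses(u, fixtab, c(0, 255)), numeric(nrow(fixtab)))
    lab_cat <- ifelse(!fixtab$is_target &
                        fixtab$item_category %in% c("face", "house"),
                      fixtab$item_category, NA)
    lab_att <- ifelse(fixtab$item_category %in% c("face", "house"),
                      ifelse(fixtab$is_target, "target", "distractor"), NA)
    hp <- hyperplane_angle(R, lab_cat, lab_att,
                           n_subsamples = 50,
                           n_shuffles = min(200, config$n_perm),
                           seed = mix_seed(config$seed, "hp"))
    note("geometry: refixation t = %.2f; hyperplane angle %.1f deg",
         cc$paired_test$statistic, hp$angle)
    out$geometry <- list(context = list(split = cc$split,
                                        t = unname(cc$paired_test$statistic),
                                        p = cc$paired_test$p.value,
                                        distance = cc$distance,
                                        angle = cc$angle),
                         hyperplane = list(angle = hp$angle, p = hp$p))
  }
  if ("encoding" %in% stages) {
    tab <- out$classify$labels
    peri <- which(tab$rf_class == "peripheral_localized")
    fits <- list()
    for (i in peri) {
      des <- build_design(s, s$units[[i]], s$units[[i]]$rf_locations)
      if (is.null(des) || length(des$y) < 40) next
      fits[[tab$unit_id[i]]] <-
        fit_lasso_splits(des, n_splits = 20,
                         seed = mix_seed(config$seed, "lasso", i))
    }
    if (length(fits) >= 10) {
      cm <- do.call(rbind, lapply(fits, `[[`, "coef_mean"))
      ass <- attention_subspace_summary(cm,
                                        seed = mix_seed(config$seed, "enc"))
      note("encoding: %d units; distance target %.2f vs distractor %.2f",
           length(fits), ass$target_state$distance,
           ass$distractor_state$distance)
      out$encoding <- list(n_units = length(fits),
                           distance_target = ass$target_state$distance,
                           distance_distractor = ass$distractor_state$distance,
                           distance_p = ass$distance_test$p.value,
                           angle_p = ass$angle_test$p.value)
    } else {
      note("encoding: only %d units with fits; geometry summary skipped",
           length(fits))
      out$encoding <- list(n_units = length(fits))
    }
  }
  if ("rsa" %in% stages) {
    pdm <- physical_dm(s$array_geometry)
    ndms <- neural_dm(s, foveal())
    tests <- lapply(seq_along(ndms), function(i)
      rsa_correlation_test(ndms[[i]], pdm, n_perm = config$n_perm,
                           seed = mix_seed(config$seed, "rsa", i)))
    note("rsa: rho = %s", paste(sprintf("%.2f", vapply(tests, `[[`, 0, "rho")),
                                collapse = ", "))
    out$rsa <- list(rho = vapply(tests, `[[`, 0, "rho"),
                    p = vapply(tests, `[[`, 0, "p"),
                    significant = vapply(tests, `[[`, TRUE, "significant"))
  }
  if ("efficiency" %in% stages) {
    et <- efficiency_table(s)
    res <- list(prop_positive = mean(et$class == "positive"),
                prop_negative = mean(et$class == "negative"))
    if (!is.null(s$lfp)) {
      th_c <- theta_power_correlation(s, "cue")
      th_d <- theta_power_correlation(s, "delay")
      res$theta <- list(cue_r = th_c$r, cue_p = th_c$p,
                        delay_r = th_d$r, delay_p = th_d$p)
      note("efficiency: %.0f%% pos, %.0f%% neg; theta r cue %.2f delay %.2f",
           100 * res$prop_positive, 100 * res$prop_negative, th_c$r, th_d$r)
    }
    res$table <- et
    out$efficiency <- res
  }
  ver <- tryCatch(as.character(utils::packageVersion("popdyn")),
                  error = function(e) "dev")
  bundle <- structure(list(stages = out, config = config, log = logline,
                           version = ver),
                      class = "pipeline_result")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    writeLines(logline, file.path(config$out_dir, "pipeline.log"))
    slim <- out
    slim$classify$labels <- NULL
    slim$efficiency$table <- NULL
    jsonlite::write_json(slim, file.path(config$out_dir, "results.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    if (!is.null(out$classify))
      utils::write.csv(out$classify$labels,
                       file.path(config$out_dir, "unit_labels.csv"),
                       row.names = FALSE)
    if (!is.null(out$efficiency$table))
      utils::write.csv(out$efficiency$table,
                       file.path(config$out_dir, "efficiency.csv"),
                       row.names = FALSE)
  }
  bundle
}
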