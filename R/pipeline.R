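#' Run the evolution and/or structure analysis pipeline
#'
#' Orchestrates the full workflow from a configuration list or YAML file.
#' The evolution track runs the radical/conservative partition sweep,
#' refits the branch and site models at the AIC-best partition, and runs
#' the ancestral convergence screen for the configured lineages. The
#' structure track computes the pressure differences of isothermal
#' compressibility, RMSF, and quasiharmonic entropy, plus conformational
#' energy when term columns are present. Each stage is fail-soft: an error
#' is recorded in the summary and dependent stages are skipped.
#'
#' Configuration keys (evolution track): `alignment`, `tree` (paths),
#' `fg_clades` (list of tip-label vectors), `scale` (path, optional),
#' `P_grid`, `posterior_threshold`, `lineages` (named list of
#' `list(parent_tips=, child_tips=)` clade specs), `estimate_branch_lengths`,
#' `restarts`. Structure track: `series_low`, `series_high`,
#' `trajectory_low`, `trajectory_high` (paths), `energy_terms`,
#' `temperature`. Global: `seed`, `out_dir`.
#'
#' @param config A list or path to a YAML file.
#' @return Invisibly, the summary list (also written as
#'   `summary.json` in `out_dir`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  out_dir <- config$out_dir %||% stop("config needs out_dir")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1L
  summary <- list(package = "rhodopress",
                  version = as.character(utils::packageVersion("rhodopress")),
                  seed = seed, stages = list())
  meta <- c(paste("rhodopress", summary$version), paste("seed", seed))

  record <- function(stage, result) {
    summary$stages[[stage]] <<- result
  }
  run_stage <- function(stage, expr) {
    res <- tryCatch(list(status = "ok", value = expr),
                    error = function(e) list(status = "error",
                                             message = conditionMessage(e)))
    record(stage, res[setdiff(names(res), "value")])
    if (res$status == "ok") res$value else NULL
  }

  # ---- evolution track ----
  if (!is.null(config$alignment)) {
    evo <- run_stage("inputs", {
      aln <- read_codon_alignment(config$alignment)
      tree <- read_tagged_tree(config$tree,
                               fg_clades = config$fg_clades)
      scale <- if (is.null(config$scale)) k0_scale()
               else read_property_scale(config$scale)
      list(aln = aln, tree = tree, scale = scale)
    })
    if (!is.null(evo)) {
      P_grid <- config$P_grid %||% seq(10, 90, by = 10)
      ebl <- isTRUE(config$estimate_branch_lengths)
      restarts <- config$restarts %||% 3
      sweep <- run_stage("partition_sweep", {
        sw <- sweep_partitions(evo$aln, evo$tree, evo$scale,
                               model_kind = "branch", P_grid = P_grid,
                               estimate_branch_lengths = ebl,
                               restarts = restarts, seed = seed)
        .write_report(sw$table, file.path(out_dir, "partition_sweep.tsv"),
                      c(meta, paste("best_P", sw$best_P)))
        sw
      })
      if (!is.null(sweep)) {
        summary$best_P <- sweep$best_P
        part <- build_partition(evo$scale, sweep$best_P)
        branch <- sweep$fits[[as.character(sweep$best_P)]]
        run_stage("branch_model", {
          cmp <- compare_models(branch$null, branch$alternative)
          est <- branch$alternative$estimates
          df <- data.frame(
            model = c("null", "alternative"),
            loglik = c(branch$null$loglik, branch$alternative$loglik),
            AIC = c(branch$null$AIC, branch$alternative$AIC),
            kappa = c(branch$null$estimates$kappa, est$kappa),
            omega = c(branch$null$estimates$omega, est$omega),
            gamma = c(branch$null$estimates$gamma, NA),
            gamma_fg = c(NA, est$gamma_fg), gamma_bg = c(NA, est$gamma_bg))
          .write_report(df, file.path(out_dir, "branch_model.tsv"),
                        c(meta, sprintf("LRT 2dl=%.4f df=%d p=%.4g",
                                        cmp$lrt, cmp$df, cmp$p_value)))
          list(lrt = cmp$lrt, p_value = cmp$p_value,
               gamma_fg = est$gamma_fg, gamma_bg = est$gamma_bg)
        })
        site <- run_stage("site_model", {
          sf <- fit_site_model(evo$aln, evo$tree, part,
                               estimate_branch_lengths = ebl,
                               restarts = restarts, seed = seed)
          .write_report(sf$posterior,
                        file.path(out_dir, "site_posteriors.tsv"), meta)
          sf
        })
        if (!is.null(site) && !is.null(config$lineages)) {
          run_stage("convergence_screen", {
            thr <- config$posterior_threshold %||% 0.95
            lins <- lapply(config$lineages, function(ln) {
              list(parent = mrca_node(evo$tree, unlist(ln$parent_tips)),
                   child = mrca_node(evo$tree, unlist(ln$child_tips)))
            })
            nodes <- unique(unlist(lapply(lins, unlist)))
            mix <- site$alternative$estimates$mixture
            post <- marginal_ancestral_states(
              evo$aln, evo$tree,
              list(kappa = site$alternative$estimates$kappa),
              part, mixture = mix, nodes = nodes)
            scr <- convergence_screen(post, lins, evo$scale,
                                      site_posterior = site$posterior,
                                      posterior_threshold = thr)
            .write_report(scr$candidates,
                          file.path(out_dir, "convergence_candidates.tsv"),
                          c(meta, paste("posterior_threshold", thr),
                            paste("reconstruction",
                                  "marginal, fitted codon model")))
            list(n_candidates = length(unique(scr$candidates$site)),
                 candidate_sites = unique(scr$candidates$site))
          })
        }
      }
    }
  }

  # ---- structure track ----
  if (!is.null(config$series_low) || !is.null(config$trajectory_low)) {
    constants <- thermo_constants(
      temperature = config$temperature %||% 300)
    if (!is.null(config$series_low)) {
      run_stage("compressibility", {
        lo <- read_ensemble_series(config$series_low)
        hi <- read_ensemble_series(config$series_high)
        dk <- delta_compressibility(hi, lo, constants)
        df <- data.frame(quantity = "delta_kappa_T_GPa",
                         value = dk$delta, sd = dk$sd,
                         low = dk$low$value, high = dk$high$value)
        .write_report(df, file.path(out_dir, "compressibility.tsv"), meta)
        list(delta_kappa_T = dk$delta)
      })
      run_stage("conformational_energy", {
        lo <- read_ensemble_series(config$series_low)
        hi <- read_ensemble_series(config$series_high)
        terms <- config$energy_terms %||% energy_terms_default()
        terms <- intersect(terms, intersect(names(lo), names(hi)))
        if (!length(terms)) stop("no energy term columns present")
        el <- conformational_energy(lo, terms, constants)
        eh <- conformational_energy(hi, terms, constants)
        df <- data.frame(quantity = "delta_E_conf_kcal",
                         value = eh$value - el$value,
                         sd = sqrt(eh$block_sd^2 + el$block_sd^2))
        .write_report(df, file.path(out_dir, "conformational_energy.tsv"),
                      meta)
        list(delta_E_conf = df$value)
      })
    }
    if (!is.null(config$trajectory_low)) {
      run_stage("rmsf", {
        lo <- read_trajectory_pdb(config$trajectory_low)
        hi <- read_trajectory_pdb(config$trajectory_high)
        dr <- delta_rmsf(hi, lo)
        .write_report(dr$per_residue, file.path(out_dir, "rmsf.tsv"),
                      c(meta, sprintf("mean_delta %.6g", dr$mean_delta)))
        list(mean_delta_rmsf = dr$mean_delta)
      })
      run_stage("entropy", {
        lo <- read_trajectory_pdb(config$trajectory_low)
        hi <- read_trajectory_pdb(config$trajectory_high)
        es <- entropy_shift(hi, lo, constants)
        df <- data.frame(quantity = "minus_T_delta_S_kcal",
                         value = es$minus_T_delta_S,
                         S_high = es$S_high, S_low = es$S_low)
        .write_report(df, file.path(out_dir, "entropy.tsv"), meta)
        list(minus_T_delta_S = es$minus_T_delta_S)
      })
    }
  }

  json <- jsonlite::toJSON(summary, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, null = "null")
  writeLines(json, file.path(out_dir, "summary.json"))
  invisible(summary)
}
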