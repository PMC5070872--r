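#' Stepwise covariate selection for the occupancy model
#'
#' Runs the five-step protocol used to choose suitability covariates:
#' \enumerate{
#'   \item fit the non-spatial model with the environmental (climate /
#'     topographic) covariates;
#'   \item keep the significant ones and refit;
#'   \item add the human-impact covariates to the significant environmental
#'     set;
#'   \item keep the significant human-impact covariates and refit;
#'   \item fit the final spatial (iCAR) model with the retained
#'     environmental and human-impact covariates.
#' }
#' A covariate is significant when zero lies outside the central 95%
#' credible interval of its coefficient posterior. Before step 1, candidate
#' pairs with Pearson |r| > `cor_cutoff` are pruned, keeping the first of
#' each offending pair in input order (deterministic tie-break). If no
#' covariate survives, the final model is intercept + iCAR, with a warning.
#'
#' @param effort Cell-effort tibble.
#' @param covariates Tibble with `cell_id` and all candidate columns
#'   (full landscape for mapping).
#' @param env_names,human_names Candidate covariate names, partitioned into
#'   environmental and human-impact sets.
#' @param grid [landscape_grid()] for the final spatial fit.
#' @param cor_cutoff Pearson correlation pre-filter threshold (default 0.7).
#' @param mcmc An [mcmc_control()] used for every fit in the protocol.
#' @param seed Integer seed.
#' @inheritParams fit_zib
#' @return A list: `report` (tibble: step, model, term, estimate, CI,
#'   significant, retained), `retained_env`, `retained_human`,
#'   `dropped_correlated`, and `final_fit` (the step-5 `zib_fit`).
#' @export
select_covariates <- function(effort, covariates, env_names, human_names,
                              grid, cor_cutoff = 0.7,
                              prior_beta_var = 1e6,
                              mcmc = mcmc_control(), seed = 1L) {
  all_names <- c(env_names, human_names)
  miss <- setdiff(all_names, names(covariates))
  if (length(miss) > 0)
    abort(paste0("Candidate covariate(s) not found: ", paste(miss, collapse = ", ")))

  ## correlation pre-filter on the cells that carry effort
  idx <- match(effort$cell_id, covariates$cell_id)
  cand <- as.matrix(covariates[idx, all_names, drop = FALSE])
  kept <- character(0)
  for (nm in all_names) {
    if (length(kept) == 0 ||
        all(abs(stats::cor(cand[, nm], cand[, kept, drop = FALSE])) <= cor_cutoff))
      kept <- c(kept, nm)
  }
  dropped_cor <- setdiff(all_names, kept)
  env_k <- intersect(env_names, kept)
  hum_k <- intersect(human_names, kept)

  sig_terms <- function(fit) {
    s <- fit$summary
    s <- s[!s$term %in% c("(Intercept)", "delta", "V_rho"), ]
    s$term[s$conf.low > 0 | s$conf.high < 0]
  }
  report_rows <- function(step, model, fit, retained) {
    s <- fit$summary
    s <- s[!s$term %in% c("delta", "V_rho"), ]
    tibble::tibble(step = step, model = model, term = s$term,
                   estimate = s$estimate, conf.low = s$conf.low,
                   conf.high = s$conf.high,
                   significant = s$conf.low > 0 | s$conf.high < 0,
                   retained = s$term %in% retained)
  }

  rep_list <- list()
  ## step 1: environmental candidates
  sig_env <- character(0)
  if (length(env_k) > 0) {
    f1 <- fit_zib(effort, covariates, env_k, prior_beta_var, mcmc, seed)
    sig_env <- sig_terms(f1)
    rep_list[[1]] <- report_rows(1L, "ZIB env", f1, sig_env)
  }
  ## step 2: refit with significant environmental covariates
  if (length(sig_env) > 0) {
    f2 <- fit_zib(effort, covariates, sig_env, prior_beta_var, mcmc, seed + 1L)
    sig_env <- sig_terms(f2)
    rep_list[[2]] <- report_rows(2L, "ZIB env (significant)", f2, sig_env)
  }
  ## step 3: add human-impact candidates
  sig_hum <- character(0)
  if (length(hum_k) > 0) {
    f3 <- fit_zib(effort, covariates, c(sig_env, hum_k), prior_beta_var,
                  mcmc, seed + 2L)
    sig_hum <- intersect(sig_terms(f3), hum_k)
    rep_list[[3]] <- report_rows(3L, "ZIB env+human", f3, c(sig_env, sig_hum))
  }
  ## step 4: refit with significant human-impact covariates
  final_set <- c(sig_env, sig_hum)
  if (length(sig_hum) > 0) {
    f4 <- fit_zib(effort, covariates, final_set, prior_beta_var, mcmc, seed + 3L)
    rep_list[[4]] <- report_rows(4L, "ZIB env+human (significant)", f4, final_set)
  }
  ## step 5: final spatial model
  if (length(final_set) == 0)
    warn("No covariate survived selection; final model is intercept + iCAR.")
  f5 <- fit_zib_icar(effort, covariates, grid, covariate_names = final_set,
                     prior_beta_var = prior_beta_var, mcmc = mcmc,
                     seed = seed + 4L)
  rep_list[[5]] <- report_rows(5L, "ZIB.iCAR final", f5, final_set)

  list(report = dplyr::bind_rows(rep_list),
       retained_env = sig_env, retained_human = sig_hum,
       dropped_correlated = dropped_cor,
       final_fit = f5)
}
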