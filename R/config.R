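#' Validate a JSON run configuration
#'
#' Reads a single JSON file describing a full run — model key, prior box,
#' qualitative conditions, quantitative fitness measures, simulation and
#' MCMC settings — and either returns the validated `hfm_run_config` or
#' stops with a message listing every schema violation found.
#'
#' Schema (all sections except `model` and `prior` optional):
#' \preformatted{
#' {
#'   "model":      {"key": "toy"},
#'   "prior":      {"reference": {"k_d": 1.0, "k_p": 1.0, "K": 0.5},
#'                  "factor": 10}
#'               or {"names": [...], "log10_lower": [...],
#'                   "log10_upper": [...]},
#'   "conditions": [{"name": "B",
#'                   "clauses": [{"input": 0.2, "n_stable": 2,
#'                                "n_unstable": 1,
#'                                "thresholds": [{"state": "Y",
#'                                  "branch": "lower", "cmp": "<=",
#'                                  "value": 1.0}]}]}],
#'   "fitness":    [{"type": "histogram", "file": "te.csv"},
#'                  {"type": "lognormal", "mean": 23, "sd": 10,
#'                   "observable": {"kind": "switching_time", "state": "Y"}}],
#'   "simulation": {"input": 1.0, "t_end": 100, "dt": 0.01},
#'   "generator":  {"n_replicates": 10000, "noise_variance": 1,
#'                  "n_bins": 50},
#'   "mcmc":       {"n_steps": 3300000, "burn_in": 300000, "thin": 3,
#'                  "sigma_q": 0.5, "proposal": "uniform"},
#'   "bifurcate":  {"inputs": [0, 0.1, 0.2]},
#'   "seed":       1
#' }
#' }
#'
#' @param path path to the JSON config file.
#' @return an `hfm_run_config`: list with `model`, `prior`, `conditions`,
#'   `fitness`, `sim`, `generator`, `mcmc`, `bifurcate` and `seed`.
#' @export
validate_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                  error = function(e) stop("malformed JSON: ",
                                           conditionMessage(e)))
  errs <- character()
  add <- function(msg) errs <<- c(errs, msg)

  model <- NULL
  if (is.null(cfg$model$key)) add("model: missing key") else {
    model <- tryCatch(hfm_model(cfg$model$key),
                      error = function(e) { add(conditionMessage(e)); NULL })
  }

  prior <- NULL
  pr <- cfg$prior
  if (is.null(pr)) add("prior: section missing") else {
    prior <- tryCatch({
      if (!is.null(pr$reference)) {
        param_vector(unlist(pr$reference),
                     factor = if (is.null(pr$factor)) 10 else pr$factor)
      } else {
        nms <- unlist(pr$names)
        lo <- unlist(pr$log10_lower); up <- unlist(pr$log10_upper)
        if (is.null(nms) || is.null(lo) || is.null(up) ||
            length(lo) != length(nms) || length(up) != length(nms))
          stop("prior: need names, log10_lower, log10_upper of equal length")
        init <- if (!is.null(pr$log10_init)) unlist(pr$log10_init)
                else (lo + up) / 2
        param_vector(stats::setNames(init, nms), lower = lo, upper = up,
                     log10 = TRUE)
      }
    }, error = function(e) { add(conditionMessage(e)); NULL })
    if (!is.null(prior) && !is.null(model) &&
        !setequal(prior$names, model$param_names))
      add(sprintf("prior: parameters (%s) do not match model parameters (%s)",
                  paste(prior$names, collapse = ","),
                  paste(model$param_names, collapse = ",")))
  }

  conditions <- list()
  for (i in seq_along(cfg$conditions)) {
    co <- cfg$conditions[[i]]
    res <- tryCatch({
      clauses <- lapply(seq_along(co$clauses), function(k) {
        cz <- co$clauses[[k]]
        if (is.null(cz$input) || is.null(cz$n_stable))
          stop(sprintf("condition %s clause %d: needs input and n_stable",
                       co$name, k))
        ths <- lapply(cz$thresholds, function(th) {
          if (!is.null(model) && !th$state %in% model$state_names)
            stop(sprintf("condition %s clause %d: unknown state '%s'",
                         co$name, k, th$state))
          state_threshold(th$state, th$branch, th$cmp, th$value)
        })
        clause(cz$input, cz$n_stable,
               if (is.null(cz$n_unstable)) 0 else cz$n_unstable, ths)
      })
      condition_spec(if (is.null(co$name)) paste0("C", i) else co$name,
                     clauses)
    }, error = function(e) { add(conditionMessage(e)); NULL })
    if (!is.null(res)) conditions <- c(conditions, list(res))
  }

  fitness <- list()
  for (i in seq_along(cfg$fitness)) {
    fi <- cfg$fitness[[i]]
    res <- tryCatch({
      if (identical(fi$type, "histogram")) {
        if (is.null(fi$file)) stop(sprintf("fitness %d: histogram needs a file", i))
        fpath <- if (file.exists(fi$file)) fi$file
                 else file.path(dirname(path), fi$file)
        if (!file.exists(fpath))
          stop(sprintf("fitness %d: missing fitness file '%s'", i, fi$file))
        read_histogram_fitness(fpath)
      } else if (identical(fi$type, "lognormal")) {
        lognormal_fitness(.obs_from_json(fi$observable, model, i),
                          fi$mean, fi$sd)
      } else stop(sprintf("fitness %d: unknown type '%s'", i, fi$type))
    }, error = function(e) { add(conditionMessage(e)); NULL })
    if (!is.null(res)) fitness <- c(fitness, list(res))
  }

  mcmc <- tryCatch({
    mc <- cfg$mcmc
    if (is.null(mc)) mcmc_config() else
      do.call(mcmc_config, mc[intersect(names(mc),
        c("n_steps", "burn_in", "thin", "sigma_q", "proposal", "init",
          "steady_grid"))])
  }, error = function(e) { add(paste0("mcmc: ", conditionMessage(e))); NULL })

  if (length(errs))
    stop("invalid run config:\n  - ", paste(errs, collapse = "\n  - "),
         call. = FALSE)
  structure(list(model = model, prior = prior, conditions = conditions,
                 fitness = fitness,
                 sim = lapply(cfg$simulation, function(x)
                   if (length(x) > 1) unlist(x) else x),
                 generator = cfg$generator, mcmc = mcmc,
                 bifurcate = cfg$bifurcate,
                 seed = cfg$seed, path = path),
            class = "hfm_run_config")
}

.obs_from_json <- function(o, model, i) {
  if (is.null(o$kind)) stop(sprintf("fitness %d: observable needs a kind", i))
  if (!is.null(model) && !is.null(o$state) &&
      !o$state %in% model$state_names)
    stop(sprintf("fitness %d: unknown state '%s'", i, o$state))
  switch(o$kind,
         execution_time = obs_execution_time(o$state,
           if (is.null(o$fraction)) 0.9 else o$fraction),
         switching_time = obs_switching_time(o$state,
           if (is.null(o$lo)) 0.025 else o$lo,
           if (is.null(o$hi)) 0.975 else o$hi),
         endpoint = obs_endpoint(o$state,
           if (is.null(o$time)) 100 else o$time),
         parameter = obs_parameter(o$name,
           if (is.null(o$scale)) "log10" else o$scale),
         stop(sprintf("fitness %d: unknown observable kind '%s'", i, o$kind)))
}
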