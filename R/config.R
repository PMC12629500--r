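# YAML model configuration: neuron parameters, input pools, correlation
# blocks, and (optionally) durations/seeds for simulation runs.

#' Read a model configuration from YAML
#'
#' Expected schema:
#' ```yaml
#' neuron: {tau: 0.015, Ve: 60, Vi: -10, Irest: 0}
#' pools:
#'   - {kind: e, K: 1000, w: 0.001, r: 10}
#'   - {kind: i, K: 250,  w: 0.004, r: 10}
#' correlation:
#'   rho: [[0.03, 0.0], [0.0, 0.03]]
#' duration: 100
#' ```
#'
#' @param path YAML file path.
#' @return A list with `params` ([neuron_params()]), `pools` (list of
#'   [input_pool()]), `corr` ([correlation_spec()]), and any extra scalar
#'   fields (e.g. `duration`, `seed`) passed through.
#' @export
read_model_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  parse_model_config(cfg)
}

#' Parse an already-loaded model configuration list
#'
#' @param cfg List with `neuron`, `pools`, and optional `correlation`
#'   entries (see [read_model_config()]).
#' @return Same structure as [read_model_config()].
#' @export
parse_model_config <- function(cfg) {
  np <- cfg$neuron %||% list()
  params <- neuron_params(
    tau = np$tau %||% 0.015, Ve = np$Ve %||% 60,
    Vi = np$Vi %||% -10, Irest = np$Irest %||% 0
  )
  pools <- lapply(cfg$pools, function(p) {
    input_pool(p$kind, p$K, p$w, p$r)
  })
  corr <- NULL
  if (!is.null(cfg$correlation)) {
    rho <- do.call(rbind, lapply(cfg$correlation$rho, as.numeric))
    corr <- correlation_spec(rho, names = cfg$correlation$names)
  } else if (length(pools) > 0) {
    corr <- correlation_spec(diag(0, length(pools)))
  }
  extras <- cfg[setdiff(names(cfg), c("neuron", "pools", "correlation"))]
  c(list(params = params, pools = pools, corr = corr), extras)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize a discrete-atom jump model to JSON
#'
#' Atoms are written as `[We vector, Wi vector, probability]` triples with
#' the event rate and labels, and can be read back with
#' [jump_model_from_json()].
#'
#' @param jm A discrete-atom [jump_model()].
#' @param path Output file.
#' @export
jump_model_to_json <- function(jm, path) {
  stopifnot(inherits(jm, "jump_model"), jm$backend == "atoms")
  obj <- list(
    labels = jm$labels, b = jm$b,
    atoms = lapply(seq_along(jm$prob), function(k) {
      list(We = unname(jm$We[k, ]), Wi = unname(jm$Wi[k, ]),
           prob = jm$prob[k])
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a discrete-atom jump model from JSON
#'
#' @param path File written by [jump_model_to_json()].
#' @return A [jump_model()].
#' @export
jump_model_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  We <- do.call(rbind, lapply(obj$atoms, function(a) unlist(a$We)))
  Wi <- do.call(rbind, lapply(obj$atoms, function(a) unlist(a$Wi)))
  prob <- vapply(obj$atoms, function(a) a$prob, numeric(1))
  jump_model(obj$b, We, Wi, prob, labels = unlist(obj$labels))
}
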