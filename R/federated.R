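#' Federated-averaging configuration
#'
#' @param n_troops number of simulated nodes ("troops"), each holding a
#'   private local dataset.
#' @param rounds federated rounds (broadcast, local training, aggregation).
#' @param local_epochs_per_round local training epochs per round (default 1,
#'   so one round is comparable to one centralized epoch of a single node).
#' @return validated list of class \code{"FederatedConfig"}.
#' @export
federatedConfig <- function(n_troops, rounds, local_epochs_per_round = 1L) {
  if (n_troops < 1) stop("'n_troops' must be >= 1")
  if (rounds < 1) stop("'rounds' must be >= 1")
  structure(list(n_troops = as.integer(n_troops),
                 rounds = as.integer(rounds),
                 local_epochs_per_round = as.integer(local_epochs_per_round)),
            class = "FederatedConfig")
}

#' One plain gradient step
#'
#' The generic local-update rule theta <- theta - eta * g.  The GAN and DAE
#' local loops use their own optimizers (RMSprop, Adam), which are this rule
#' with adaptive per-parameter step sizes.
#'
#' @param theta numeric vector/array (or list of them).
#' @param grad gradient of the local loss at \code{theta}, same shape.
#' @param eta learning rate.
#' @return updated parameters, same shape as \code{theta}.
#' @examples
#' sgdStep(0, grad = -4, eta = 0.1)   # 0.4
#' @export
sgdStep <- function(theta, grad, eta) {
  if (is.list(theta)) return(Map(function(t, g) t - eta * g, theta, grad))
  theta - eta * grad
}

#' Sample-count-weighted parameter aggregation
#'
#' The server-side federated-averaging rule: the global parameters are the
#' weighted mean of the local parameters with weights s_i / s (s_i = local
#' sample count, s = total).  Computed as
#' \code{p_1 + sum_i w_i (p_i - p_1)}, algebraically identical since the
#' weights sum to 1, and exactly the identity when all locals agree.  The
#' function receives only parameter containers and counts -- never spectra --
#' which is the no-raw-data contract of federated learning.
#'
#' @param params_list non-empty list; each element is a named list of numeric
#'   arrays (one troop's parameters), all shape-identical.
#' @param sample_counts positive numeric vector, one count per troop.
#' @return named list of aggregated parameter arrays.
#' @examples
#' federatedAverage(list(list(w = 0), list(w = 4)), c(1, 3))   # w = 3
#' @export
federatedAverage <- function(params_list, sample_counts) {
  if (!length(params_list)) stop("'params_list' must be non-empty")
  if (length(sample_counts) != length(params_list))
    stop("one sample count per parameter set is required")
  if (any(sample_counts <= 0)) stop("sample counts must be positive")
  w <- sample_counts / sum(sample_counts)
  out <- params_list[[1L]]
  nms <- names(out)
  for (i in seq_along(params_list)) {
    pi <- params_list[[i]]
    if (!is.list(pi) || isS4(pi) ||
        !all(vapply(pi, is.numeric, logical(1))))
      stop("each parameter container must be a plain named list of ",
           "numeric arrays; raw data never reaches the aggregator")
    if (!identical(names(pi), nms) ||
        !all(vapply(nms, function(nm)
          identical(dim(pi[[nm]]), dim(out[[nm]])) &&
          length(pi[[nm]]) == length(out[[nm]]), logical(1))))
      stop("parameter sets must be shape-identical across troops")
    if (i > 1L)
      for (nm in nms) out[[nm]] <- out[[nm]] + w[i] * (pi[[nm]] - params_list[[1L]][[nm]])
  }
  out
}

# materialize/extract the aggregatable state of a model-kind
.fed_get <- function(state, kind) {
  if (kind == "gan")
    list(trainable = c(G = list(nn_trainable(state$G)),
                       D = list(nn_trainable(state$D))),
         buffers = list(G = nn_buffers(state$G), D = nn_buffers(state$D)))
  else
    list(trainable = list(model = nn_trainable(state$model)),
         buffers = list(model = nn_buffers(state$model)))
}

.fed_set <- function(state, kind, agg) {
  if (kind == "gan") {
    state$G <- nn_set_trainable(state$G, agg$trainable$G)
    state$D <- nn_set_trainable(state$D, agg$trainable$D)
    state$G <- nn_set_buffers(state$G, agg$buffers$G)
    state$D <- nn_set_buffers(state$D, agg$buffers$D)
  } else {
    state$model <- nn_set_trainable(state$model, agg$trainable$model)
    state$model <- nn_set_buffers(state$model, agg$buffers$model)
  }
  state
}

#' One troop's local training pass
#'
#' Loads the broadcast global parameters into the troop's local model, runs
#' the model's own training loop (GAN or DAE semantics) for
#' \code{local_epochs} on the troop's private data, and returns the updated
#' parameters.  Raw spectra never leave the troop.
#'
#' @param troop a troop state created inside
#'   \code{\link{runFederatedTraining}}: a list with the local model state
#'   (\code{$state}), the local data matrix (\code{$data}) and sample count
#'   (\code{$s}).
#' @param global_params aggregated parameter container from
#'   \code{\link{federatedAverage}} (with buffers), or NULL on the first
#'   round.
#' @param local_epochs local epochs to run; 0 returns the loaded parameters
#'   unchanged.
#' @param model_kind \code{"gan"} or \code{"dae"}.
#' @return the updated troop (with advanced model, optimizer and RNG state).
#' @export
localUpdate <- function(troop, global_params, local_epochs, model_kind) {
  if (!is.null(global_params))
    troop$state <- .fed_set(troop$state, model_kind, global_params)
  if (local_epochs > 0) {
    troop$state <- if (model_kind == "gan")
      gan_run_epochs(troop$state, troop$data, local_epochs)
    else
      dae_run_epochs(troop$state, troop$data, local_epochs)
  }
  troop
}

#' Simulated federated training of the GAN or DAE
#'
#' One global model is initialized from \code{model_cfg$rng_seed}; each round
#' it is broadcast to every troop, each troop trains locally on its private
#' dataset, and the server aggregates the returned parameters by
#' sample-count-weighted averaging (generator and critic aggregated
#' separately for the GAN).  Batch-norm running statistics are aggregated
#' with the same weights.  Local optimizer moments and RNG streams persist at
#' each troop across rounds, so a single-troop federation reproduces
#' centralized training bit for bit.
#'
#' @param troop_data list of \linkS4class{SpectrumSet}s or matrices, one per
#'   troop (uniform spectrum length; [0, 1] intensity scale).
#' @param model_kind \code{"gan"} or \code{"dae"}.
#' @param fed_cfg a \code{\link{federatedConfig}} (its \code{n_troops} must
#'   match \code{length(troop_data)}).
#' @param model_cfg a \code{\link{ganConfig}} or \code{\link{daeConfig}}.
#' @param monitor optional \code{function(global_state, round, troops)}
#'   evaluated after each aggregation (\code{troops} holds the post-update
#'   local states, so a troop-level readout -- "the result data of one troop"
#'   -- is available); its value is recorded in the history.
#' @param stop_value optional threshold: training stops early once
#'   \code{monitor} returns a value >= \code{stop_value}.
#' @return list with \code{global} (a \code{"ganState"}/\code{"daeState"}
#'   holding the aggregated global model), \code{history} (per-round
#'   data.frame: round, mean local loss per troop, aggregation weights,
#'   monitor value) and \code{rounds_run}.
#' @export
runFederatedTraining <- function(troop_data, model_kind = c("gan", "dae"),
                                 fed_cfg, model_cfg, monitor = NULL,
                                 stop_value = NULL) {
  model_kind <- match.arg(model_kind)
  if (!length(troop_data)) stop("'troop_data' must be non-empty")
  if (fed_cfg$n_troops != length(troop_data))
    stop("fed_cfg$n_troops must match length(troop_data)")
  mats <- lapply(troop_data, function(d)
    if (is(d, "SpectrumSet")) intensities(d) else d)
  L <- unique(vapply(mats, nrow, integer(1)))
  if (length(L) != 1L) stop("all troops must hold spectra of one length")
  if (model_kind == "gan") mats <- lapply(mats, function(m) 2 * m - 1)

  global <- if (model_kind == "gan") gan_init(model_cfg) else dae_init(model_cfg)
  rng0 <- global$rng
  troops <- lapply(seq_along(mats), function(i) {
    st <- global
    if (i > 1L) {
      old <- .save_rng()
      set.seed(model_cfg$rng_seed + i)
      st$rng <- get(".Random.seed", envir = globalenv())
      .restore_rng(old)
    } else st$rng <- rng0
    list(troop_id = i, state = st, data = mats[[i]], s = ncol(mats[[i]]))
  })
  counts <- vapply(troops, `[[`, numeric(1), "s")
  w <- counts / sum(counts)

  history <- list()
  agg <- NULL
  rounds_run <- 0L
  for (r in seq_len(fed_cfg$rounds)) {
    troops <- lapply(troops, localUpdate, global_params = agg,
                     local_epochs = fed_cfg$local_epochs_per_round,
                     model_kind = model_kind)
    locals <- lapply(troops, function(tr) .fed_get(tr$state, model_kind))
    agg <- list(
      trainable = lapply(names(locals[[1L]]$trainable), function(part)
        federatedAverage(lapply(locals, function(l) l$trainable[[part]]),
                         counts)),
      buffers = lapply(names(locals[[1L]]$buffers), function(part)
        federatedAverage(lapply(locals, function(l) l$buffers[[part]]),
                         counts)))
    names(agg$trainable) <- names(locals[[1L]]$trainable)
    names(agg$buffers) <- names(locals[[1L]]$buffers)
    global <- .fed_set(global, model_kind, agg)
    rounds_run <- r
    loss <- vapply(troops, function(tr) {
      h <- tr$state$history
      if (model_kind == "gan") h[[length(h)]][["gen_loss"]]
      else h[[length(h)]]
    }, numeric(1))
    mon <- if (is.null(monitor)) NA_real_ else monitor(global, r, troops)
    history[[r]] <- data.frame(round = r,
                               troop = seq_along(troops),
                               local_loss = loss,
                               weight = w,
                               monitor = mon)
    if (!is.null(stop_value) && !is.na(mon) && mon >= stop_value) break
  }
  list(global = global, history = do.call(rbind, history),
       rounds_run = rounds_run)
}
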