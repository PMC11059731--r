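#' Neural gas configuration
#'
#' Hyperparameters of the neural gas vector quantizer. The defaults follow the
#' settings used for BMU analysis of CLR-transformed pufM communities: five
#' units, 1000 training epochs, initial step size 0.5 and initial decay
#' (neighbourhood) constant 4.5. The annealing endpoints `eps_final` and
#' `lambda_final` make late training nearly winner-only.
#'
#' @param k_units number of codebook units ("BMUs").
#' @param epochs full passes over the data.
#' @param eps_initial,eps_final step-size schedule endpoints.
#' @param lambda_initial,lambda_final neighbourhood-range schedule endpoints.
#' @param seed integer seed driving initialization and presentation order.
#' @return an `ng_config` list.
#' @export
ng_config <- function(k_units = 5, epochs = 1000, eps_initial = 0.5,
                      eps_final = 0.005, lambda_initial = 4.5,
                      lambda_final = 0.01, seed = 1) {
  if (!is_count(k_units)) stop_("k_units must be a positive integer")
  if (!is_count(epochs)) stop_("epochs must be a positive integer")
  if (!(eps_final > 0 && eps_final <= eps_initial && eps_initial <= 1)) {
    stop_("need 0 < eps_final <= eps_initial <= 1")
  }
  if (!(lambda_final > 0 && lambda_final <= lambda_initial)) {
    stop_("need 0 < lambda_final <= lambda_initial")
  }
  structure(list(k_units = as.integer(k_units), epochs = as.integer(epochs),
                 eps_initial = eps_initial, eps_final = eps_final,
                 lambda_initial = lambda_initial, lambda_final = lambda_final,
                 seed = as.integer(seed)),
            class = "ng_config")
}

# All randomness of a training run: initial codebook rows and the per-epoch
# presentation orders, drawn once from the config seed.
ng_draws <- function(n, k_units, epochs, seed) {
  with_seed(seed, {
    init <- sample.int(n, k_units)
    pres <- as.vector(vapply(seq_len(epochs), function(e) sample.int(n),
                             integer(n)))
    list(init = init, pres = pres)
  })
}

#' Train a neural gas model
#'
#' Online rank-based vector quantization: the codebook is initialized at
#' `k_units` distinct data rows chosen by the seeded generator; in each epoch
#' samples are presented in a fresh seeded random order; for every presented
#' sample all units are ranked by Euclidean distance (ties to the lower unit
#' index) and updated by `w_i += eps(t) * exp(-rank_i/lambda(t)) * (x - w_i)`,
#' with exponentially annealed `eps` and `lambda` on the presentation clock
#' `t = 1..epochs*n`. Fully reproducible from the config seed.
#'
#' @param X numeric matrix (samples x features), typically a CLR matrix.
#' @param config an [ng_config()].
#' @return an `ng_model` with elements `codebook` (k x p, rows `U1..Uk`),
#'   `config`, `quantization_error` (final, on `X`), `qe_initial`
#'   (of the initial codebook), `n_presentations` and `init_indices`.
#' @export
train_neural_gas <- function(X, config = ng_config()) {
  if (!is.matrix(X) || !is.numeric(X)) stop_("X must be a numeric matrix")
  if (anyNA(X) || any(!is.finite(X))) stop_("X has non-finite values")
  n <- nrow(X)
  if (config$k_units > n) {
    stop_(sprintf("k_units (%d) exceeds the number of samples (%d)",
                  config$k_units, n))
  }
  draws <- ng_draws(n, config$k_units, config$epochs, config$seed)
  W0 <- X[draws$init, , drop = FALSE]
  W <- ng_train_cpp(X, W0, draws$pres,
                    config$eps_initial, config$eps_final,
                    config$lambda_initial, config$lambda_final)
  rownames(W) <- paste0("U", seq_len(config$k_units))
  colnames(W) <- colnames(X)
  structure(list(codebook = W, config = config,
                 quantization_error = ng_quantization_error_cpp(X, W),
                 qe_initial = ng_quantization_error_cpp(X, W0),
                 n_presentations = length(draws$pres),
                 init_indices = draws$init),
            class = "ng_model")
}

#' @export
print.ng_model <- function(x, ...) {
  cat(sprintf("Neural gas model: %d units x %d features\n",
              nrow(x$codebook), ncol(x$codebook)))
  cat(sprintf("  epochs %d (%d presentations), eps %.3g -> %.3g, lambda %.3g -> %.3g, seed %d\n",
              x$config$epochs, x$n_presentations, x$config$eps_initial,
              x$config$eps_final, x$config$lambda_initial,
              x$config$lambda_final, x$config$seed))
  cat(sprintf("  quantization error %.4f (initial %.4f)\n",
              x$quantization_error, x$qe_initial))
  invisible(x)
}

codebook_of <- function(model) {
  if (inherits(model, "ng_model")) model$codebook else model
}

#' Assign samples to their best-matching unit
#'
#' Each sample is mapped to the nearest codebook unit (Euclidean distance);
#' ties go to the lowest unit index. A unit together with its member samples
#' is one "BMU" (characteristic distribution).
#'
#' @param model an `ng_model` (or a bare codebook matrix).
#' @param X data matrix in the model's feature space.
#' @return `bmu_assignment`: named integer vector (sample -> unit index) with
#'   attribute `k_units`.
#' @export
assign_bmu <- function(model, X) {
  W <- codebook_of(model)
  if (ncol(X) != ncol(W)) {
    stop_(sprintf("feature mismatch: data has %d features, codebook %d",
                  ncol(X), ncol(W)))
  }
  # squared distances via ||x||^2 - 2 x.w + ||w||^2; which.min takes the
  # first (lowest-index) minimum, which is the documented tie-break
  cross <- X %*% t(W)
  d2 <- outer(rowSums(X^2), rep(1, nrow(W))) - 2 * cross +
    outer(rep(1, nrow(X)), rowSums(W^2))
  units <- apply(d2, 1, which.min)
  structure(as.integer(units), names = rownames(X), k_units = nrow(W),
            class = "bmu_assignment")
}

#' @export
print.bmu_assignment <- function(x, ...) {
  k <- attr(x, "k_units")
  tab <- tabulate(unclass(x), nbins = k)
  cat(sprintf("BMU assignment: %d samples in %d units (%s)\n",
              length(x), k, paste0("U", seq_len(k), "=", tab, collapse = ", ")))
  invisible(x)
}

#' Members of each unit
#' @param assignment a `bmu_assignment`.
#' @return list of sample-id character vectors, one per unit (empty units
#'   included).
#' @export
bmu_members <- function(assignment) {
  k <- attr(assignment, "k_units") %||% max(assignment)
  lapply(seq_len(k), function(u) names(assignment)[unclass(assignment) == u])
}

#' Quantization error
#'
#' Mean Euclidean distance from each sample to its nearest codebook unit.
#'
#' @param model an `ng_model` or bare codebook matrix.
#' @param X data matrix.
#' @return non-negative scalar.
#' @export
quantization_error <- function(model, X) {
  W <- codebook_of(model)
  if (ncol(X) != ncol(W)) stop_("feature space mismatch")
  ng_quantization_error_cpp(X, W)
}

#' Renumber units by decreasing membership
#'
#' Relabels units so that U1 is the most populated, ties keeping the original
#' order; deterministic. Reported BMU tables become comparable across runs.
#'
#' @param model an `ng_model`.
#' @param assignment the matching `bmu_assignment`.
#' @return list with relabelled `model` and `assignment`.
#' @export
relabel_units <- function(model, assignment) {
  k <- nrow(model$codebook)
  membership <- tabulate(unclass(assignment), nbins = k)
  ord <- order(-membership, seq_len(k))
  new_of_old <- match(seq_len(k), ord)
  model$codebook <- model$codebook[ord, , drop = FALSE]
  rownames(model$codebook) <- paste0("U", seq_len(k))
  model$init_indices <- model$init_indices[ord]
  new_assignment <- structure(new_of_old[unclass(assignment)],
                              names = names(assignment), k_units = k,
                              class = "bmu_assignment")
  list(model = model, assignment = new_assignment)
}
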