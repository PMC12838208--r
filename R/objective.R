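#' Configuration of the GC-constrained training objective
#'
#' Parameters of the augmented-Lagrangian objective
#' `L_total = L_MLM + lambda * (GC - mu) + (rho / 2) * (GC - mu)^2`
#' and of its scheduled dual/penalty updates. The GC target `mu` defaults to
#' 0.52, the optimum for E. coli expression; constraint terms are disabled
#' during a curriculum warm-up (first `warmup_epochs` epochs) and the
#' multiplier/penalty are updated every `update_every_steps` optimization
#' steps thereafter.
#'
#' @param mu Target GC fraction (default 0.52).
#' @param epsilon Violation tolerance: `|GC_sm - mu|` below this counts as
#'   satisfied.
#' @param eta Relative-improvement threshold; the penalty grows only when the
#'   violation shrank by less than this fraction since the last scheduled
#'   update.
#' @param p_inc Penalty multiplier (> 1).
#' @param rho_min,rho_max Bounds for the penalty coefficient.
#' @param rho_init,lambda_init Initial penalty and multiplier.
#' @param warmup_epochs Curriculum warm-up epochs with constraint terms off
#'   (default 3).
#' @param update_every_steps Scheduled-update cadence in steps (default 20).
#' @param smoothing_alpha EMA coefficient for the smoothed GC estimate.
#' @param gc_estimator How the differentiable GC estimate is formed. The
#'   constrained quantity is the GC content of the sequences the model emits,
#'   so the default `"straight_through"` evaluates the batch GC on the
#'   argmax codons (exactly what greedy decoding will produce) while routing
#'   the gradient through the soft expectation, which never saturates.
#'   `"sharpened"` takes the expectation under temperature-`gc_temperature`
#'   distributions; `"expectation"` is the plain probability-weighted mean.
#' @param gc_temperature Softmax temperature of the `"sharpened"` estimator
#'   (1 recovers the plain expectation).
#' @param gc_in_loss `"batch"` (default) uses the raw per-batch GC estimate in
#'   the loss, `"smoothed"` uses the EMA; scheduling always uses the EMA.
#' @export
constraint_config <- function(mu = 0.52, epsilon = 0.005, eta = 0.05,
                              p_inc = 2, rho_min = 0.1, rho_max = 100,
                              rho_init = 1, lambda_init = 0,
                              warmup_epochs = 3L, update_every_steps = 20L,
                              smoothing_alpha = 0.1,
                              gc_estimator = c("straight_through", "sharpened",
                                               "expectation"),
                              gc_temperature = 0.25,
                              gc_in_loss = c("batch", "smoothed")) {
  stopifnot(mu > 0, mu < 1, epsilon >= 0, p_inc > 1,
            rho_min <= rho_init, rho_init <= rho_max,
            smoothing_alpha > 0, smoothing_alpha <= 1,
            gc_temperature > 0, update_every_steps >= 1)
  structure(list(mu = mu, epsilon = epsilon, eta = eta, p_inc = p_inc,
                 rho_min = rho_min, rho_max = rho_max, rho_init = rho_init,
                 lambda_init = lambda_init, warmup_epochs = as.integer(warmup_epochs),
                 update_every_steps = as.integer(update_every_steps),
                 smoothing_alpha = smoothing_alpha,
                 gc_estimator = match.arg(gc_estimator),
                 gc_temperature = gc_temperature,
                 gc_in_loss = match.arg(gc_in_loss)),
            class = "constraint_config")
}

#' Initialize the augmented-Lagrangian state
#'
#' Holds the multiplier `lambda`, penalty `rho`, smoothed GC estimate,
#' current deviation/violation, relative improvement, counters, and an
#' append-only history log.
#'
#' @param config A [constraint_config()].
#' @return A `lagrangian_state` list.
#' @export
lagrangian_state <- function(config = constraint_config()) {
  structure(list(
    lambda_k = config$lambda_init,
    rho_k = config$rho_init,
    gc_sm = NA_real_,
    delta_k = NA_real_,
    v_k = NA_real_,
    v_prev = NA_real_,    # violation at the previous scheduled update
    r_k = NA_real_,
    step = 0L,
    epoch = 0L,
    history = list()
  ), class = "lagrangian_state")
}

#' Masked-language-modeling loss
#'
#' Mean negative natural-log probability of the gold token over the masked
#' positions: `-(1/|M|) * sum_i log p(x_i* | context)`. Probabilities are
#' floored at `prob_floor` before the log for numerical safety (a warning is
#' emitted when the floor engages).
#'
#' @param batch List with `distributions` (matrix, masked positions x
#'   vocabulary tokens, rows summing to 1, token names as column names) and
#'   `gold` (character vector of gold tokens, one per row).
#' @param prob_floor Lower clamp inside the log.
#' @return Scalar loss (>= 0).
#' @export
mlm_loss <- function(batch, prob_floor = 1e-12) {
  p <- batch$distributions
  stopifnot(is.matrix(p), length(batch$gold) == nrow(p))
  idx <- cbind(seq_len(nrow(p)), match(batch$gold, colnames(p)))
  if (anyNA(idx[, 2])) stop("gold token not in vocabulary columns")
  pg <- p[idx]
  if (any(pg < prob_floor)) {
    warning("gold-token probability below floor; clamped at ", prob_floor)
    pg <- pmax(pg, prob_floor)
  }
  -mean(log(pg))
}

#' Differentiable expected GC content of predicted distributions
#'
#' Mean over predicted positions of the probability-weighted token GC
#' fractions — a linear function of the distributions, hence differentiable
#' with respect to any parameters behind them. With one-hot rows it equals
#' the literal GC content of the decoded codons.
#'
#' @param distributions Matrix, positions x vocabulary tokens (columns named).
#' @param vocab A [build_vocabulary()] object.
#' @return Expected GC fraction in `[0, 1]`.
#' @export
expected_gc <- function(distributions, vocab = build_vocabulary()) {
  g <- vocab$gc_fraction[colnames(distributions)]
  mean(as.vector(distributions %*% g))
}

#' Update the smoothed GC estimate
#'
#' Exponential moving average `GC_sm <- (1 - alpha) * GC_sm + alpha * gc`;
#' the first observation initializes `GC_sm = gc`.
#'
#' @param state A [lagrangian_state()].
#' @param batch_gc Expected GC of the current batch, in `[0, 1]`.
#' @param config A [constraint_config()].
#' @return The updated state (also refreshes `delta_k` and `v_k`).
#' @export
smooth_gc <- function(state, batch_gc, config) {
  stopifnot(batch_gc >= 0, batch_gc <= 1)
  a <- config$smoothing_alpha
  state$gc_sm <- if (is.na(state$gc_sm)) batch_gc
                 else (1 - a) * state$gc_sm + a * batch_gc
  state$delta_k <- state$gc_sm - config$mu
  state$v_k <- abs(state$delta_k)
  state
}

#' Total augmented-Lagrangian loss breakdown
#'
#' During warm-up the constraint terms are zero and `l_total = l_mlm`;
#' afterwards `l_total = l_mlm + lambda * (gc - mu) + (rho / 2) * (gc - mu)^2`.
#'
#' @param l_mlm MLM loss value.
#' @param gc Expected GC used in the loss (see `gc_in_loss` in
#'   [constraint_config()]).
#' @param state A [lagrangian_state()] providing `lambda_k`, `rho_k`.
#' @param config A [constraint_config()].
#' @param in_warmup Logical; when `TRUE` constraint terms vanish.
#' @return A `loss_breakdown` list: `l_mlm`, `expected_gc`, `linear_term`,
#'   `quadratic_term`, `l_total`.
#' @export
total_loss <- function(l_mlm, gc, state, config, in_warmup = FALSE) {
  if (in_warmup) {
    lin <- 0; quad <- 0
  } else {
    d <- gc - config$mu
    lin <- state$lambda_k * d
    quad <- state$rho_k / 2 * d^2
  }
  structure(list(l_mlm = l_mlm, expected_gc = gc,
                 linear_term = lin, quadratic_term = quad,
                 l_total = l_mlm + lin + quad),
            class = "loss_breakdown")
}

#' Scheduled dual-variable update
#'
#' `lambda_{k+1} = lambda_k + rho_k * delta_k` where `delta_k = GC_sm - mu`:
#' the multiplier grows when GC runs above target (pushing probability toward
#' low-GC codons) and shrinks when below.
#'
#' @param state A [lagrangian_state()] with current `delta_k`.
#' @return The updated state.
#' @export
dual_update <- function(state) {
  stopifnot(!is.na(state$delta_k))
  state$lambda_k <- state$lambda_k + state$rho_k * state$delta_k
  state
}

#' Scheduled adaptive penalty update
#'
#' When the violation persists (`v_k > epsilon`) and the relative improvement
#' since the previous scheduled update is inadequate (`r_k < eta`), the
#' penalty is multiplied by `p_inc` and clamped into `[rho_min, rho_max]`;
#' otherwise it is left unchanged. `r_k = (v_prev - v_k) / max(v_prev, floor)`
#' with a small floor against division by zero.
#'
#' @param state A [lagrangian_state()] with current `v_k` and `v_prev`.
#' @param config A [constraint_config()].
#' @param floor Denominator floor for `r_k`.
#' @return The updated state (with `r_k` refreshed and `v_prev` rolled over).
#' @export
penalty_update <- function(state, config, floor = 1e-8) {
  stopifnot(!is.na(state$v_k))
  state$r_k <- if (is.na(state$v_prev)) Inf
               else (state$v_prev - state$v_k) / max(state$v_prev, floor)
  if (state$v_k > config$epsilon && state$r_k < config$eta) {
    state$rho_k <- min(max(config$rho_min, state$rho_k * config$p_inc),
                       config$rho_max)
  }
  state$v_prev <- state$v_k
  state
}

#' Decide whether the current step triggers scheduled updates
#'
#' Returns `"dual_and_penalty_update"` iff the warm-up is over
#' (`epoch > warmup_epochs`, epochs 1-based) and the step counter is a
#' multiple of the cadence; `"none"` otherwise. A history row is appended
#' either way.
#'
#' @param state A [lagrangian_state()] with current `step`, `epoch`.
#' @param config A [constraint_config()].
#' @param extra Optional named list merged into the history row (e.g. losses).
#' @return List with `action` and the updated `state`.
#' @export
schedule_step <- function(state, config, extra = list()) {
  action <- if (state$epoch > config$warmup_epochs &&
                state$step %% config$update_every_steps == 0L)
    "dual_and_penalty_update" else "none"
  row <- c(list(step = state$step, epoch = state$epoch,
                lambda = state$lambda_k, rho = state$rho_k,
                gc_sm = state$gc_sm, v = state$v_k, r = state$r_k),
           extra)
  state$history[[length(state$history) + 1L]] <- row
  list(action = action, state = state)
}

#' Collect the state history as a data frame
#'
#' @param state A [lagrangian_state()].
#' @return Data frame, one row per logged step.
#' @export
history_df <- function(state) {
  if (length(state$history) == 0L) return(data.frame())
  cols <- unique(unlist(lapply(state$history, names)))
  out <- lapply(cols, function(cn) {
    vapply(state$history, function(r) {
      v <- r[[cn]]
      if (is.null(v) || is.na(v)) NA_real_ else as.numeric(v)
    }, numeric(1))
  })
  names(out) <- cols
  as.data.frame(out)
}
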