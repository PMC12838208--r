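ctx_symbols <- function(vocab) {
  c(sort(setdiff(names(vocab$families), "*")), "*", "^", "$")
}

#' Trainable reference codon-prediction backend
#'
#' A compact conditional model standing in for a large masked language model:
#' for each masked residue it produces logits over the residue's synonymous
#' codon family, parameterized by the amino-acid identity plus (with
#' `context_width = 1`) additive features of the neighboring residues.
#' Probability mass outside the masked amino acid's family is exactly zero by
#' construction, so every decoded sequence translates back to the input
#' protein. Untrained, every family is uniform. The model is differentiable;
#' training uses the analytic softmax gradients.
#'
#' @param vocab A [build_vocabulary()] object.
#' @param context_width 0 (amino-acid identity only) or 1 (plus left/right
#'   neighbor features).
#' @return A `ref_backend` list with `vocab`, `context_width`, `params`
#'   (per-family `base` logits and optional `L`/`R` context matrices) and
#'   family lookup tables.
#' @export
reference_backend <- function(vocab = build_vocabulary(), context_width = 1L) {
  stopifnot(context_width %in% c(0L, 1L))
  fam_names <- names(vocab$families)
  ctx <- ctx_symbols(vocab)
  params <- lapply(fam_names, function(aa) {
    nc <- length(vocab$families[[aa]])
    p <- list(base = numeric(nc))
    if (context_width >= 1L) {
      p$L <- matrix(0, length(ctx), nc)
      p$R <- matrix(0, length(ctx), nc)
    }
    p
  })
  names(params) <- fam_names
  fam_info <- lapply(fam_names, function(aa) {
    toks <- vocab$families[[aa]]
    list(tokens = toks,
         codons = unname(vocab$codon_of[toks]),
         gc_frac = unname(vocab$gc_fraction[toks]),
         gc_count = as.integer(round(3 * unname(vocab$gc_fraction[toks]))))
  })
  names(fam_info) <- fam_names
  structure(list(vocab = vocab, context_width = context_width,
                 ctx = ctx, params = params, fam_info = fam_info,
                 trainable = TRUE),
            class = "ref_backend")
}

#' @export
print.ref_backend <- function(x, ...) {
  cat("ref_backend: context_width =", x$context_width, "(",
      sum(vapply(x$params, function(p) length(unlist(p)), numeric(1))),
      "parameters )\n")
  invisible(x)
}

# Residue strings (with terminal "*" when a stop is modeled) to index triples.
encode_residues <- function(backend, residues) {
  n <- length(residues)
  left <- c("^", residues[-n])
  right <- c(residues[-1], "$")
  list(aa = residues,
       l = match(left, backend$ctx),
       r = match(right, backend$ctx))
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Per-position family probabilities for a residue vector.
# Returns a list (one element per position) of named probability vectors over
# the family's codons (lexicographic codon order).
position_probs <- function(backend, residues) {
  enc <- encode_residues(backend, residues)
  out <- vector("list", length(residues))
  for (aa in unique(enc$aa)) {
    idx <- which(enc$aa == aa)
    p <- backend$params[[aa]]
    info <- backend$fam_info[[aa]]
    z <- matrix(p$base, length(idx), length(p$base), byrow = TRUE)
    if (backend$context_width >= 1L) {
      z <- z + p$L[enc$l[idx], , drop = FALSE] + p$R[enc$r[idx], , drop = FALSE]
    }
    pr <- softmax_rows(z)
    for (k in seq_along(idx)) {
      out[[idx[k]]] <- stats::setNames(pr[k, ], info$codons)
    }
  }
  out
}

#' Full-vocabulary predicted distributions for a protein
#'
#' Expands the per-family predictions to distributions over the whole token
#' vocabulary (zero mass outside the masked residue's synonymous family),
#' the representation consumed by [mlm_loss()] and [expected_gc()].
#'
#' @param backend A [reference_backend()].
#' @param protein Amino-acid string (optionally ending in `*`).
#' @return Matrix, residues x vocabulary tokens.
#' @export
predict_distributions <- function(backend, protein) {
  res <- protein_residues(protein)
  vocab <- backend$vocab
  probs <- position_probs(backend, res)
  m <- matrix(0, length(res), length(vocab$tokens),
              dimnames = list(NULL, vocab$tokens))
  for (i in seq_along(res)) {
    toks <- vocab$families[[res[i]]]
    m[i, toks] <- probs[[i]]
  }
  m
}

# Split a protein string into residue letters; trailing "*" kept as residue.
protein_residues <- function(protein) {
  p <- toupper(protein)
  res <- strsplit(p, "")[[1]]
  if (any(res == "*" & seq_along(res) < length(res))) {
    stop("internal '*' in protein")
  }
  res
}

#' Training configuration for the reference backend
#'
#' Defaults mirror a transformer-scale fine-tuning recipe (15 epochs, batch
#' size 6, learning rate 5e-5, cosine annealing with warm restarts); for the
#' compact reference backend a much larger learning rate (0.5--1) is
#' appropriate and used by the package's own experiments (see the methods
#' vignette).
#'
#' @param epochs Training epochs.
#' @param batch_size Sequences per optimization step.
#' @param learning_rate Base step size.
#' @param scheduler List: `type` (`"cosine_restarts"` or `"constant"`),
#'   `t0` (steps of the first cycle; `NULL` = one epoch), `t_mult` (cycle
#'   growth factor), `eta_min_frac` (floor as a fraction of the base rate).
#' @param mask_ratio Fraction of positions masked per sequence and step
#'   (1 = predict every codon, matching the inference task).
#' @param plateau_threshold,patience Convergence monitor: relative
#'   validation-loss improvement below the threshold for `patience`
#'   consecutive epochs flags a plateau (reported, not an early stop).
#' @param seed Integer seed.
#' @export
training_config <- function(epochs = 15L, batch_size = 6L,
                            learning_rate = 5e-5,
                            scheduler = list(type = "cosine_restarts",
                                             t0 = NULL, t_mult = 2,
                                             eta_min_frac = 0.1),
                            mask_ratio = 1,
                            plateau_threshold = 0.005, patience = 2L,
                            seed = 1L) {
  stopifnot(epochs >= 0, batch_size >= 1, learning_rate > 0,
            mask_ratio > 0, mask_ratio <= 1)
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, scheduler = scheduler,
                 mask_ratio = mask_ratio,
                 plateau_threshold = plateau_threshold,
                 patience = as.integer(patience), seed = as.integer(seed)),
            class = "training_config")
}

lr_at <- function(step, steps_per_epoch, tc) {
  sch <- tc$scheduler
  if (is.null(sch) || identical(sch$type, "constant")) return(tc$learning_rate)
  t0 <- if (is.null(sch$t0)) max(steps_per_epoch, 1L) else sch$t0
  tm <- if (is.null(sch$t_mult)) 2 else sch$t_mult
  eta_min <- tc$learning_rate * (if (is.null(sch$eta_min_frac)) 0.1
                                 else sch$eta_min_frac)
  # locate position within the current warm-restart cycle
  s <- step - 1L
  ti <- t0
  while (s >= ti) {
    s <- s - ti
    ti <- ti * tm
  }
  eta_min + (tc$learning_rate - eta_min) * (1 + cos(pi * s / ti)) / 2
}

# Tokenize a CDS into training positions: residues (incl terminal "*"),
# per-position gold codon index within the family, context indices.
prepare_example <- function(backend, dna) {
  toks <- tokenize_cds(dna, backend$vocab)
  res <- unname(backend$vocab$aa_of[toks])
  enc <- encode_residues(backend, res)
  gold <- vapply(seq_along(toks), function(i) {
    match(toks[i], backend$vocab$families[[res[i]]])
  }, integer(1))
  list(aa = res, l = enc$l, r = enc$r, gold = gold)
}

#' Train the reference backend with the GC-constrained objective
#'
#' Minibatch gradient descent on
#' `L_total = L_MLM + lambda * (GC - mu) + (rho / 2) * (GC - mu)^2`, where GC
#' is the batch-level expected GC of the predicted distributions. Constraint
#' terms are off during the curriculum warm-up; afterwards the multiplier and
#' penalty undergo scheduled updates at the configured cadence, driven by the
#' smoothed GC estimate. Deterministic given the seed. Per-step state is
#' logged; per-epoch train/validation MLM losses are logged with plateau
#' detection.
#'
#' @param dataset Character vector of valid CDS (or data frame with a
#'   `sequence` column).
#' @param backend A [reference_backend()].
#' @param tc A [training_config()].
#' @param cc A [constraint_config()].
#' @param val_dataset Optional held-out CDS for validation-loss monitoring.
#' @return List: `backend` (trained), `state` (final [lagrangian_state()]),
#'   `history` (per-step data frame), `epoch_log` (per-epoch data frame with
#'   `plateau` flags), `baseline_val_mlm` (untrained validation loss).
#' @export
train <- function(dataset, backend, tc = training_config(),
                  cc = constraint_config(), val_dataset = NULL) {
  if (is.data.frame(dataset)) dataset <- dataset$sequence
  if (length(dataset) == 0L) stop("empty training dataset")
  if (is.data.frame(val_dataset)) val_dataset <- val_dataset$sequence

  examples <- lapply(dataset, function(d) prepare_example(backend, d))
  val_examples <- if (!is.null(val_dataset)) {
    lapply(val_dataset, function(d) prepare_example(backend, d))
  }
  state <- lagrangian_state(cc)
  steps_per_epoch <- max(1L, ceiling(length(examples) / tc$batch_size))
  baseline_val <- if (!is.null(val_examples)) eval_mlm(backend, val_examples)
  epoch_log <- list()
  prev_val <- NA_real_
  plateau_run <- 0L

  if (tc$epochs == 0L) {
    return(list(backend = backend, state = state, history = history_df(state),
                epoch_log = data.frame(), baseline_val_mlm = baseline_val))
  }
  set.seed(tc$seed)
  for (epoch in seq_len(tc$epochs)) {
    state$epoch <- epoch
    in_warmup <- epoch <= cc$warmup_epochs
    ord <- sample.int(length(examples))
    batch_starts <- seq(1L, length(ord), by = tc$batch_size)
    ep_mlm <- 0; ep_n <- 0L
    for (bs in batch_starts) {
      batch <- examples[ord[bs:min(bs + tc$batch_size - 1L, length(ord))]]
      state$step <- state$step + 1L
      lr <- lr_at(state$step, steps_per_epoch, tc)
      res <- sgd_step(backend, batch, state, cc, tc, lr, in_warmup)
      backend <- res$backend
      if (!is.finite(res$l_total)) {
        stop("non-finite loss at step ", state$step,
             "; history retained in the returned state")
      }
      state <- smooth_gc(state, res$batch_gc, cc)
      ss <- schedule_step(state, cc,
                          extra = list(l_mlm = res$l_mlm, l_total = res$l_total,
                                       batch_gc = res$batch_gc, lr = lr))
      state <- ss$state
      if (ss$action == "dual_and_penalty_update") {
        state <- dual_update(state)
        state <- penalty_update(state, cc)
      }
      ep_mlm <- ep_mlm + res$l_mlm
      ep_n <- ep_n + 1L
    }
    val_mlm <- if (!is.null(val_examples)) eval_mlm(backend, val_examples)
               else NA_real_
    improve <- if (is.na(prev_val) || is.na(val_mlm)) NA_real_
               else (prev_val - val_mlm) / max(abs(prev_val), 1e-12)
    plateau_run <- if (!is.na(improve) && improve < tc$plateau_threshold)
      plateau_run + 1L else 0L
    epoch_log[[epoch]] <- data.frame(
      epoch = epoch, train_mlm = ep_mlm / ep_n, val_mlm = val_mlm,
      gc_sm = state$gc_sm, lambda = state$lambda_k, rho = state$rho_k,
      plateau = plateau_run >= tc$patience)
    prev_val <- val_mlm
  }
  list(backend = backend, state = state, history = history_df(state),
       epoch_log = do.call(rbind, epoch_log), baseline_val_mlm = baseline_val)
}

# Mean MLM loss of a backend over prepared examples (no gradient).
eval_mlm <- function(backend, examples) {
  tot <- 0; n <- 0L
  for (ex in examples) {
    probs <- position_probs(backend, ex$aa)
    pg <- vapply(seq_along(ex$gold), function(i) probs[[i]][ex$gold[i]],
                 numeric(1))
    tot <- tot + sum(-log(pmax(pg, 1e-12)))
    n <- n + length(pg)
  }
  tot / n
}

# One SGD step on a batch of prepared examples; returns updated backend and
# the batch losses. Gradients are the analytic softmax gradients of
# L_MLM + coef * GC_batch with coef = lambda + rho * (GC_batch - mu); the GC
# estimate follows cc$gc_estimator (straight-through by default: hard argmax
# GC in the value, soft-expectation gradient).
sgd_step <- function(backend, batch, state, cc, tc, lr, in_warmup) {
  aa <- unlist(lapply(batch, `[[`, "aa"))
  l <- unlist(lapply(batch, `[[`, "l"))
  r <- unlist(lapply(batch, `[[`, "r"))
  gold <- unlist(lapply(batch, `[[`, "gold"))
  if (tc$mask_ratio < 1) {
    keep <- which(stats::runif(length(aa)) < tc$mask_ratio)
    if (length(keep) == 0L) keep <- sample.int(length(aa), 1L)
    aa <- aa[keep]; l <- l[keep]; r <- r[keep]; gold <- gold[keep]
  }
  M <- length(aa)
  est <- cc$gc_estimator
  tau <- if (identical(est, "sharpened")) cc$gc_temperature else 1

  fam_cache <- list()
  sum_gc <- 0
  sum_nll <- 0
  for (f in unique(aa)) {
    idx <- which(aa == f)
    p <- backend$params[[f]]
    info <- backend$fam_info[[f]]
    z <- matrix(p$base, length(idx), length(p$base), byrow = TRUE)
    if (backend$context_width >= 1L) {
      z <- z + p$L[l[idx], , drop = FALSE] + p$R[r[idx], , drop = FALSE]
    }
    pr <- softmax_rows(z)
    pr_t <- if (tau == 1) pr else softmax_rows(z / tau)
    gc_val <- if (identical(est, "straight_through")) {
      info$gc_frac[max.col(pr, ties.method = "first")]
    } else {
      as.vector(pr_t %*% info$gc_frac)
    }
    gc_grad_pos <- as.vector(pr_t %*% info$gc_frac)
    sum_gc <- sum_gc + sum(gc_val)
    pg <- pr[cbind(seq_along(idx), gold[idx])]
    sum_nll <- sum_nll - sum(log(pmax(pg, 1e-12)))
    fam_cache[[f]] <- list(idx = idx, pr = pr, pr_t = pr_t,
                           gc_grad_pos = gc_grad_pos)
  }
  batch_gc <- sum_gc / M
  l_mlm <- sum_nll / M
  coef <- if (in_warmup) 0 else
    state$lambda_k + state$rho_k * (batch_gc - cc$mu)
  lb <- total_loss(l_mlm, batch_gc, state, cc, in_warmup)

  for (f in names(fam_cache)) {
    fc <- fam_cache[[f]]
    info <- backend$fam_info[[f]]
    onehot <- matrix(0, nrow(fc$pr), ncol(fc$pr))
    onehot[cbind(seq_len(nrow(onehot)), gold[fc$idx])] <- 1
    grad <- (fc$pr - onehot) / M
    if (coef != 0) {
      grad <- grad + (coef / tau) * fc$pr_t *
        (matrix(info$gc_frac, nrow(fc$pr), ncol(fc$pr), byrow = TRUE) -
           fc$gc_grad_pos) / M
    }
    backend$params[[f]]$base <- backend$params[[f]]$base - lr * colSums(grad)
    if (backend$context_width >= 1L) {
      li <- l[fc$idx]; ri <- r[fc$idx]
      gl <- rowsum(grad, li)
      backend$params[[f]]$L[as.integer(rownames(gl)), ] <-
        backend$params[[f]]$L[as.integer(rownames(gl)), , drop = FALSE] - lr * gl
      gr <- rowsum(grad, ri)
      backend$params[[f]]$R[as.integer(rownames(gr)), ] <-
        backend$params[[f]]$R[as.integer(rownames(gr)), , drop = FALSE] - lr * gr
    }
  }
  list(backend = backend, l_mlm = l_mlm, l_total = lb$l_total,
       batch_gc = batch_gc)
}

#' Serialize / restore a backend checkpoint
#'
#' Plain-JSON checkpoint carrying the context width, all parameters, and a
#' hash of the vocabulary token list so stale checkpoints are refused.
#'
#' @param backend A [reference_backend()].
#' @param path Output JSON path.
#' @export
save_checkpoint <- function(backend, path) {
  obj <- list(
    format = "codonopt-checkpoint-v1",
    vocab_hash = vocab_hash(backend$vocab),
    context_width = backend$context_width,
    params = lapply(backend$params, function(p) lapply(p, unclass))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' @rdname save_checkpoint
#' @param vocab Vocabulary the checkpoint must match.
#' @export
load_checkpoint <- function(path, vocab = build_vocabulary()) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "codonopt-checkpoint-v1")) {
    stop("unrecognized checkpoint format")
  }
  if (!identical(obj$vocab_hash, vocab_hash(vocab))) {
    stop("checkpoint vocabulary hash does not match the current vocabulary")
  }
  backend <- reference_backend(vocab, context_width = as.integer(obj$context_width))
  for (f in names(backend$params)) {
    p <- obj$params[[f]]
    backend$params[[f]]$base <- as.numeric(p$base)
    if (backend$context_width >= 1L) {
      backend$params[[f]]$L <- matrix(as.numeric(p$L), nrow = length(backend$ctx))
      backend$params[[f]]$R <- matrix(as.numeric(p$R), nrow = length(backend$ctx))
    }
  }
  backend
}

vocab_hash <- function(vocab) {
  # order-sensitive digest of the token list (stable across sessions)
  v <- as.numeric(utf8ToInt(paste(vocab$tokens, collapse = "|")))
  as.character(sum(v * seq_along(v)) %% 2^31)
}
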