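#' Configuration of the convolutional-recurrent risk network
#'
#' The network embeds each selected 2D slice with a shared small CNN
#' backbone, averages the three slice embeddings per organ and timepoint,
#' runs a per-organ LSTM over (baseline, follow-up) for the dynamic variant,
#' concatenates the liver and lung representations, and maps them to a scalar
#' log-relative-hazard through linear layers. It is trained with the negative
#' log Cox partial likelihood.
#'
#' @param variant `"rad_d"` (baseline + follow-up through the recurrent unit)
#'   or `"rad_s"` (baseline images only, no recurrent unit).
#' @param input_size internal working resolution of the backbone; the
#'   224x224 pack images are block-mean pooled down to this side, which must
#'   divide the pack image side. Default 32.
#' @param conv_channels channel widths of the four 3x3 conv layers; 2x2 max
#'   pooling follows every conv layer except the last.
#' @param embed_dim slice embedding dimension d produced by the backbone.
#' @param recurrent_hidden LSTM hidden dimension.
#' @param head_dims widths of the linear head; must end in 1.
#' @param learning_rate Adam learning rate (default 5e-5).
#' @param batch_size minibatch size (>= 2; the partial likelihood needs a
#'   risk set). Batches at least as large as the cohort give full-batch
#'   training.
#' @param epochs training epochs (default 200).
#' @param augment_p probability of the horizontal-flip augmentation applied
#'   per image during training (default 0.5).
#' @param weight_decay L2 penalty coefficient added to the loss gradient
#'   during training (default 0; useful against overfitting on small
#'   cohorts).
#' @param n_models number of independently seeded networks trained by
#'   [train_survnet()]; for `n_models > 1` the model's score is the average
#'   of the members' training-standardized scores (a small deep ensemble,
#'   reducing the seed-to-seed variance that dominates at small n).
#' @param seed seed controlling initialization, shuffling and augmentation.
#' @return an object of class `net_config`.
#' @export
net_config <- function(variant = c("rad_d", "rad_s"),
                       input_size = 32L,
                       conv_channels = c(8L, 16L, 32L, 32L),
                       embed_dim = 64L,
                       recurrent_hidden = 32L,
                       head_dims = c(32L, 1L),
                       learning_rate = 5e-5,
                       batch_size = 16L,
                       epochs = 200L,
                       augment_p = 0.5,
                       weight_decay = 0,
                       n_models = 1L,
                       seed = 1L) {
  variant <- match.arg(variant)
  if (tail_one(head_dims) != 1L) stop("invalid config: head must end in a scalar output")
  if (epochs < 1) stop("invalid config: epochs must be >= 1")
  if (batch_size < 2) stop("invalid config: batch_size must be >= 2")
  if (input_size < 8 || input_size %% 2^(length(conv_channels) - 1L) != 0)
    stop("invalid config: input_size must be >= 8 and divisible by 2^(n_conv - 1)")
  structure(list(variant = variant, input_size = as.integer(input_size),
                 conv_channels = as.integer(conv_channels),
                 embed_dim = as.integer(embed_dim),
                 recurrent_hidden = as.integer(recurrent_hidden),
                 head_dims = as.integer(head_dims),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 augment_p = augment_p, weight_decay = weight_decay,
                 n_models = as.integer(n_models), seed = as.integer(seed)),
            class = "net_config")
}

tail_one <- function(x) x[length(x)]

# He-style initialization; one shared backbone across organs, timepoints and
# slices; separate LSTMs per organ; linear head on the concatenated organs
svn_init_params <- function(cfg) {
  with_seed(cfg$seed, {
    params <- list()
    c_in <- 1L
    for (l in seq_along(cfg$conv_channels)) {
      c_out <- cfg$conv_channels[l]
      params[[paste0("bb_convW", l)]] <-
        matrix(rnorm(9L * c_in * c_out, sd = sqrt(2 / (9 * c_in))), 9L * c_in, c_out)
      params[[paste0("bb_convb", l)]] <- numeric(c_out)
      c_in <- c_out
    }
    params$bb_fcW <- matrix(rnorm(c_in * cfg$embed_dim, sd = sqrt(2 / c_in)),
                            c_in, cfg$embed_dim)
    params$bb_fcb <- numeric(cfg$embed_dim)
    if (cfg$variant == "rad_d") {
      h <- cfg$recurrent_hidden
      for (org in ORGANS) {
        params[[paste0("lstm_", org, "_Wx")]] <-
          matrix(rnorm(cfg$embed_dim * 4L * h, sd = sqrt(1 / cfg$embed_dim)),
                 cfg$embed_dim, 4L * h)
        params[[paste0("lstm_", org, "_Wh")]] <-
          matrix(rnorm(h * 4L * h, sd = sqrt(1 / h)), h, 4L * h)
        b <- numeric(4L * h)
        b[h + seq_len(h)] <- 1 # forget-gate bias
        params[[paste0("lstm_", org, "_b")]] <- b
      }
      head_in <- 2L * h
    } else {
      head_in <- 2L * cfg$embed_dim
    }
    dims <- c(head_in, cfg$head_dims)
    for (l in seq_len(length(dims) - 1L)) {
      params[[paste0("head_W", l)]] <-
        matrix(rnorm(dims[l] * dims[l + 1L], sd = sqrt(2 / dims[l])),
               dims[l], dims[l + 1L])
      params[[paste0("head_b", l)]] <- numeric(dims[l + 1L])
    }
    params
  })
}

svn_backbone_forward <- function(img, params, cfg) {
  a <- array(img, c(dim(img), 1L))
  nl <- length(cfg$conv_channels)
  caches <- vector("list", nl)
  for (l in seq_len(nl)) {
    cv <- nn_conv_forward(a, params[[paste0("bb_convW", l)]],
                          params[[paste0("bb_convb", l)]])
    r <- pmax(cv$out, 0)
    caches[[l]] <- list(conv = cv, mask = cv$out > 0)
    if (l < nl) {
      mp <- nn_maxpool_forward(r)
      caches[[l]]$pool <- mp
      a <- mp$out
    } else {
      caches[[l]]$act <- r # last conv activations (Grad-CAM target)
      a <- r
    }
  }
  sp <- dim(a)
  dim(a) <- c(sp[1] * sp[2], sp[3])
  gap <- colMeans(a)
  emb <- nn_dense_forward(gap, params$bb_fcW, params$bb_fcb)
  list(emb = emb, caches = caches, gap = gap, act_dim = sp)
}

# returns param grads plus the gradient at the last conv activations
svn_backbone_backward <- function(fw, params, cfg, demb) {
  grads <- list()
  fc <- nn_dense_backward(fw$gap, params$bb_fcW, demb)
  grads$bb_fcW <- fc$dW; grads$bb_fcb <- fc$db
  sp <- fw$act_dim
  da <- array(rep(fc$dx, each = sp[1] * sp[2]) / (sp[1] * sp[2]), sp)
  nl <- length(cfg$conv_channels)
  dact <- NULL
  for (l in rev(seq_len(nl))) {
    cache <- fw$caches[[l]]
    dr <- if (l < nl) nn_maxpool_backward(cache$pool, da) else da
    if (l == nl) dact <- dr
    dconv <- dr * cache$mask
    bk <- nn_conv_backward(cache$conv, params[[paste0("bb_convW", l)]], dconv,
                           need_dx = l > 1L)
    grads[[paste0("bb_convW", l)]] <- bk$dW
    grads[[paste0("bb_convb", l)]] <- bk$db
    da <- bk$dx
  }
  list(grads = grads, dact = dact)
}

# organ/timepoint keys needed by a variant
svn_keys <- function(variant) {
  tps <- if (variant == "rad_d") TIMEPOINTS else "baseline"
  unlist(lapply(ORGANS, function(o) vapply(tps, function(tp) vkey(o, tp), "")))
}

# convert a slice_pack's 224x224 images to backbone-resolution tensors
svn_pack_tensor <- function(pack, cfg) {
  side <- nrow(pack$images[[1]][[1]])
  P <- if (side == cfg$input_size) NULL else nn_pool_matrix(side, cfg$input_size)
  tens <- list()
  for (key in svn_keys(cfg$variant)) {
    imgs <- pack$images[[key]]
    if (is.null(imgs) || length(imgs) != 3L)
      stop("invalid input: pack must hold exactly 3 images per organ/timepoint")
    tens[[key]] <- lapply(imgs, function(m)
      if (is.null(P)) m else nn_downsample(m, P))
  }
  tens
}

# forward pass on backbone-resolution tensors; cache retained on request
svn_forward_tensor <- function(tens, params, cfg, keep_cache = FALSE) {
  embs <- list(); caches <- list()
  for (key in names(tens)) {
    fw3 <- lapply(tens[[key]], svn_backbone_forward, params = params, cfg = cfg)
    embs[[key]] <- Reduce(`+`, lapply(fw3, `[[`, "emb")) / 3
    if (keep_cache) caches[[key]] <- fw3
  }
  lstm_caches <- list()
  reps <- list()
  for (org in ORGANS) {
    if (cfg$variant == "rad_d") {
      lc <- nn_lstm_forward(list(embs[[vkey(org, "baseline")]],
                                 embs[[vkey(org, "followup")]]),
                            params[[paste0("lstm_", org, "_Wx")]],
                            params[[paste0("lstm_", org, "_Wh")]],
                            params[[paste0("lstm_", org, "_b")]])
      reps[[org]] <- lc$h
      lstm_caches[[org]] <- lc
    } else {
      reps[[org]] <- embs[[vkey(org, "baseline")]]
    }
  }
  z <- c(reps$liver, reps$lung)
  n_head <- length(cfg$head_dims)
  head_cache <- vector("list", n_head)
  a <- z
  for (l in seq_len(n_head)) {
    y <- nn_dense_forward(a, params[[paste0("head_W", l)]],
                          params[[paste0("head_b", l)]])
    act <- if (l < n_head) pmax(y, 0) else y
    head_cache[[l]] <- list(x = a, pre = y)
    a <- act
  }
  score <- drop(a)
  if (!keep_cache) return(list(score = score))
  list(score = score, slice_caches = caches, lstm_caches = lstm_caches,
       head_cache = head_cache, concat = z)
}

# reverse pass; returns accumulated parameter grads and, on request, the
# per-slice gradients at the last conv activations (for Grad-CAM)
svn_backward_tensor <- function(fw, params, cfg, dscore, keep_dact = FALSE) {
  grads <- list()
  n_head <- length(cfg$head_dims)
  dy <- dscore
  for (l in rev(seq_len(n_head))) {
    hc <- fw$head_cache[[l]]
    if (l < n_head) dy <- dy * (hc$pre > 0)
    bk <- nn_dense_backward(hc$x, params[[paste0("head_W", l)]], dy)
    grads[[paste0("head_W", l)]] <- bk$dW
    grads[[paste0("head_b", l)]] <- bk$db
    dy <- bk$dx
  }
  rep_dim <- length(dy) / 2L
  drep <- list(liver = dy[seq_len(rep_dim)], lung = dy[rep_dim + seq_len(rep_dim)])
  demb <- list()
  for (org in ORGANS) {
    if (cfg$variant == "rad_d") {
      lb <- nn_lstm_backward(fw$lstm_caches[[org]],
                             params[[paste0("lstm_", org, "_Wx")]],
                             params[[paste0("lstm_", org, "_Wh")]],
                             drep[[org]])
      grads[[paste0("lstm_", org, "_Wx")]] <- lb$dWx
      grads[[paste0("lstm_", org, "_Wh")]] <- lb$dWh
      grads[[paste0("lstm_", org, "_b")]] <- lb$db
      demb[[vkey(org, "baseline")]] <- lb$dxs[[1]]
      demb[[vkey(org, "followup")]] <- lb$dxs[[2]]
    } else {
      demb[[vkey(org, "baseline")]] <- drep[[org]]
    }
  }
  dacts <- list()
  for (key in names(fw$slice_caches)) {
    dk <- demb[[key]] / 3
    dacts[[key]] <- vector("list", 3L)
    for (s in 1:3) {
      bb <- svn_backbone_backward(fw$slice_caches[[key]][[s]], params, cfg, dk)
      grads <- nn_grad_add(grads, bb$grads)
      if (keep_dact) dacts[[key]][[s]] <- bb$dact
    }
  }
  list(grads = grads, dacts = dacts)
}

#' Score one slice pack with the risk network
#'
#' Deterministic given the parameters: each slice is embedded by the shared
#' backbone, slice embeddings are averaged per organ and timepoint, the
#' dynamic variant runs a per-organ LSTM over the two timepoints, liver and
#' lung representations are concatenated and mapped to a scalar
#' log-relative-hazard.
#'
#' @param pack a `slice_pack` (12 images; the static variant uses the 6
#'   baseline images).
#' @param config a [net_config()].
#' @param params parameter list from [train_survnet()] (or
#'   internal initialization).
#' @return a `risk_score`: list with `patient_id`, `score`, `variant`.
#' @export
survnet_forward <- function(pack, config, params) {
  stopifnot(inherits(pack, "slice_pack"), inherits(config, "net_config"))
  tens <- svn_pack_tensor(pack, config)
  fw <- svn_forward_tensor(tens, params, config)
  risk_score(pack$patient_id, fw$score, config$variant)
}

#' Negative log Cox partial likelihood of a score vector
#'
#' `-(1/D) * sum_{i: event} [ s_i - log sum_{j: t_j >= t_i} exp(s_j) ]` with
#' `D` the event count and the Breslow convention for tied event times.
#' Invariant to adding a constant to all scores. `cox_pl_grad()` additionally
#' returns the exact gradient in the scores, used as the training signal.
#'
#' @param scores numeric vector of log-relative-hazards.
#' @param times,events survival times and 0/1 event indicators of equal
#'   length (at least one event required).
#' @return the scalar loss; for `cox_pl_grad()` a list `(loss, grad)`.
#' @export
cox_partial_likelihood_loss <- function(scores, times, events) {
  cox_pl_grad(scores, times, events)$loss
}

#' @rdname cox_partial_likelihood_loss
#' @export
cox_pl_grad <- function(scores, times, events) {
  n <- length(scores)
  if (length(times) != n || length(events) != n || n < 2)
    stop("invalid input: scores, times, events must have equal length >= 2")
  D <- sum(events == 1)
  if (D == 0) stop("undefined loss: batch contains no events")
  smax <- max(scores)
  es <- exp(scores - smax)
  loss <- 0
  grad <- -as.numeric(events == 1)
  for (i in which(events == 1)) {
    at_risk <- times >= times[i]
    denom <- sum(es[at_risk])
    loss <- loss - (scores[i] - smax - log(denom))
    grad[at_risk] <- grad[at_risk] + es[at_risk] / denom
  }
  list(loss = loss / D, grad = grad / D)
}

#' Train the risk network with the Cox partial-likelihood loss
#'
#' Minibatch Adam on the within-batch partial likelihood (risk sets formed
#' inside each batch; batches with no events are skipped). The horizontal
#' flip augmentation is applied during training only; returned scores are
#' computed from the final parameters on the unaugmented packs.
#'
#' @param packs list of `slice_pack`s.
#' @param records data frame with `patient_id`, `os_days`, `event` covering
#'   every pack.
#' @param config a [net_config()].
#' @param verbose print the per-epoch mean loss.
#' @return an object of class `survnet_fit`: `params`, `config`,
#'   `scores` (data frame patient_id/score/variant) and the per-epoch mean
#'   training loss `history`. With `n_models > 1` the fit additionally
#'   carries the `members` (one single-network fit per seed) and their
#'   training score means/sds used for standardization; `params` then
#'   refers to the first member (used e.g. by [grad_cam()]).
#' @export
train_survnet <- function(packs, records, config, verbose = FALSE) {
  stopifnot(inherits(config, "net_config"))
  k <- config$n_models %||% 1L
  if (k > 1L) {
    members <- lapply(seq_len(k) - 1L, function(m) {
      cfg_m <- config
      cfg_m$seed <- config$seed + 1000L * m
      cfg_m$n_models <- 1L
      train_survnet_single(packs, records, cfg_m, verbose)
    })
    mu <- vapply(members, function(f) mean(f$scores$score), 0)
    sg <- vapply(members, function(f) max(sd(f$scores$score), 1e-12), 0)
    Z <- mapply(function(f, m, s) (f$scores$score - m) / s, members, mu, sg)
    structure(list(members = members, params = members[[1]]$params,
                   score_norms = data.frame(mean = mu, sd = sg),
                   config = config,
                   scores = data.frame(
                     patient_id = members[[1]]$scores$patient_id,
                     score = rowMeans(Z), variant = config$variant),
                   history = lapply(members, `[[`, "history")),
              class = "survnet_fit")
  } else {
    train_survnet_single(packs, records, config, verbose)
  }
}

train_survnet_single <- function(packs, records, config, verbose = FALSE) {
  ids <- vapply(packs, `[[`, "", "patient_id")
  ridx <- match(ids, records$patient_id)
  if (anyNA(ridx)) stop("records must cover every pack's patient_id")
  times <- records$os_days[ridx]
  events <- records$event[ridx]
  if (length(packs) < 2) stop("need at least 2 patients")
  if (sum(events) == 0) stop("training aborted: no events in the cohort")

  params <- svn_init_params(config)
  tens_all <- lapply(packs, svn_pack_tensor, cfg = config)
  state <- nn_adam_init(params)
  n <- length(packs)
  history <- numeric(config$epochs)
  set.seed(config$seed + 1L)
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    ep_loss <- 0; ep_n <- 0
    for (bt in batches) {
      if (length(bt) < 2 || sum(events[bt]) == 0) next
      tb <- lapply(tens_all[bt], function(tt) {
        if (config$augment_p <= 0) return(tt)
        lapply(tt, function(imgs) lapply(imgs, function(m)
          if (runif(1) < config$augment_p) flip_horizontal(m) else m))
      })
      fws <- lapply(tb, svn_forward_tensor, params = params, cfg = config,
                    keep_cache = TRUE)
      scores <- vapply(fws, `[[`, 0, "score")
      lg <- cox_pl_grad(scores, times[bt], events[bt])
      grads <- list()
      for (k in seq_along(bt)) {
        bk <- svn_backward_tensor(fws[[k]], params, config, lg$grad[k])
        grads <- nn_grad_add(grads, bk$grads)
      }
      wd <- config$weight_decay %||% 0
      if (wd > 0) {
        for (nm in names(grads)) grads[[nm]] <- grads[[nm]] + wd * params[[nm]]
      }
      upd <- nn_adam_step(params, grads, state, config$learning_rate)
      params <- upd$params; state <- upd$state
      ep_loss <- ep_loss + lg$loss * length(bt); ep_n <- ep_n + length(bt)
    }
    history[ep] <- if (ep_n > 0) ep_loss / ep_n else NA_real_
    if (verbose) message(sprintf("epoch %d loss %.4f", ep, history[ep]))
  }
  scores <- vapply(tens_all, function(tt)
    svn_forward_tensor(tt, params, config)$score, 0)
  structure(list(params = params, config = config,
                 scores = data.frame(patient_id = ids, score = scores,
                                     variant = config$variant),
                 history = history),
            class = "survnet_fit")
}

#' @export
print.survnet_fit <- function(x, ...) {
  if (!is.null(x$members)) {
    cat(sprintf("survnet_fit (%s): %d patients, ensemble of %d networks\n",
                x$config$variant, nrow(x$scores), length(x$members)))
  } else {
    cat(sprintf("survnet_fit (%s): %d patients, %d epochs, final loss %.4f\n",
                x$config$variant, nrow(x$scores), x$config$epochs,
                tail_one(x$history[!is.na(x$history)])))
  }
  invisible(x)
}

#' Score slice packs with a trained risk network
#'
#' @param fit a `survnet_fit`.
#' @param packs list of `slice_pack`s.
#' @return data frame with `patient_id`, `score`, `variant`.
#' @export
predict_survnet <- function(fit, packs) {
  stopifnot(inherits(fit, "survnet_fit"))
  if (!is.null(fit$members)) {
    Z <- vapply(seq_along(fit$members), function(m) {
      s <- vapply(packs, function(p)
        survnet_forward(p, fit$members[[m]]$config,
                        fit$members[[m]]$params)$score, 0)
      (s - fit$score_norms$mean[m]) / fit$score_norms$sd[m]
    }, numeric(length(packs)))
    scores <- rowMeans(matrix(Z, nrow = length(packs)))
  } else {
    scores <- vapply(packs, function(p)
      survnet_forward(p, fit$config, fit$params)$score, 0)
  }
  data.frame(patient_id = vapply(packs, `[[`, "", "patient_id"),
             score = scores, variant = fit$config$variant)
}

#' Construct a risk score
#'
#' @param patient_id patient identifier.
#' @param score scalar log-relative-hazard.
#' @param variant model tag (`cln`, `rad_s`, `rad_d`, `radcln_s`, `radcln_d`).
#' @return an object of class `risk_score`.
#' @export
risk_score <- function(patient_id, score, variant) {
  if (!is.finite(score)) stop("risk score must be finite")
  structure(list(patient_id = patient_id, score = score, variant = variant),
            class = "risk_score")
}

#' @export
print.risk_score <- function(x, ...) {
  cat(sprintf("risk_score[%s] %s: %.4f\n", x$variant, x$patient_id %||% "?", x$score))
  invisible(x)
}
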