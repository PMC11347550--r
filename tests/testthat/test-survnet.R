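test_that("config validation enforces head/batch/epoch/input constraints", {
  expect_error(net_config(head_dims = c(8, 2)), "scalar")
  expect_error(net_config(epochs = 0), "epochs")
  expect_error(net_config(batch_size = 1), "batch_size")
  expect_error(net_config(input_size = 30), "input_size")
})

test_that("cox partial-likelihood loss reproduces hand-computed values", {
  # two patients, scores (1, 0), both events: risk sets {1,2} then {2}
  expect_equal(cox_partial_likelihood_loss(c(1, 0), c(1, 2), c(1, 1)),
               (log(1 + exp(1)) - 1) / 2, tolerance = 1e-12)
  # equal scores, all events, distinct times: (1/n) sum log k, free of c
  for (c0 in c(-3, 0, 2)) {
    n <- 6
    expect_equal(cox_partial_likelihood_loss(rep(c0, n), 1:n, rep(1, n)),
                 mean(log(1:n)), tolerance = 1e-12)
  }
  expect_error(cox_partial_likelihood_loss(c(1, 0), c(1, 2), c(0, 0)), "no events")
})

test_that("loss is shift-invariant and matches an offset-only Cox model", {
  skip_if_not_installed("survival")
  set.seed(8)
  for (r in 1:5) {
    n <- 12
    s <- rnorm(n); tt <- rexp(n); ev <- rbinom(n, 1, 0.7)
    if (sum(ev) == 0) ev[1] <- 1
    l0 <- cox_partial_likelihood_loss(s, tt, ev)
    expect_equal(cox_partial_likelihood_loss(s + 17.3, tt, ev), l0, tolerance = 1e-10)
    ref <- survival::coxph(survival::Surv(tt, ev) ~ offset(s), ties = "breslow")
    expect_equal(l0, -ref$loglik[1] / sum(ev), tolerance = 1e-9)
  }
})

test_that("loss gradient matches central finite differences", {
  set.seed(9)
  for (r in 1:10) {
    n <- sample(3:10, 1)
    s <- rnorm(n); tt <- sample(n); ev <- rbinom(n, 1, 0.6)
    if (sum(ev) == 0) ev[sample(n, 1)] <- 1
    g <- cox_pl_grad(s, tt, ev)$grad
    eps <- 1e-6
    for (k in seq_len(n)) {
      sp <- s; sp[k] <- sp[k] + eps
      sm <- s; sm[k] <- sm[k] - eps
      fd <- (cox_partial_likelihood_loss(sp, tt, ev) -
               cox_partial_likelihood_loss(sm, tt, ev)) / (2 * eps)
      # absolute floor absorbs FD round-off on exactly-zero gradients
      # (patients censored before every event time)
      expect_lt(abs(fd - g[k]) / max(abs(fd), abs(g[k]), 1e-5), 1e-4)
    }
  }
})

test_that("network gradient matches finite differences end to end", {
  cfg <- net_config(variant = "rad_d", input_size = 8,
                    conv_channels = c(2, 3, 2, 2), embed_dim = 4,
                    recurrent_hidden = 3, head_dims = c(3, 1), seed = 5)
  params <- ctprog:::svn_init_params(cfg)
  set.seed(42)
  t1 <- fake_tensor(cfg, 1); t2 <- fake_tensor(cfg, 2)
  times <- c(2, 1); events <- c(1, 1)
  loss_of <- function(p) {
    s <- c(ctprog:::svn_forward_tensor(t1, p, cfg)$score,
           ctprog:::svn_forward_tensor(t2, p, cfg)$score)
    cox_partial_likelihood_loss(s, times, events)
  }
  fw1 <- ctprog:::svn_forward_tensor(t1, params, cfg, keep_cache = TRUE)
  fw2 <- ctprog:::svn_forward_tensor(t2, params, cfg, keep_cache = TRUE)
  lg <- cox_pl_grad(c(fw1$score, fw2$score), times, events)
  g <- ctprog:::nn_grad_add(
    ctprog:::svn_backward_tensor(fw1, params, cfg, lg$grad[1])$grads,
    ctprog:::svn_backward_tensor(fw2, params, cfg, lg$grad[2])$grads)
  # eps small enough that the central difference does not step across a
  # ReLU/max-pool kink for this seed
  eps <- 1e-6
  for (nm in names(params)) {
    for (ix in sample(length(params[[nm]]), min(3, length(params[[nm]])))) {
      p2 <- params
      p2[[nm]][ix] <- p2[[nm]][ix] + eps; up <- loss_of(p2)
      p2[[nm]][ix] <- p2[[nm]][ix] - 2 * eps; dn <- loss_of(p2)
      fd <- (up - dn) / (2 * eps)
      expect_lt(abs(fd - g[[nm]][ix]) / max(abs(fd), abs(g[[nm]][ix]), 1e-6),
                1e-4)
    }
  }
})

test_that("forward is deterministic, slice-order invariant, and LOCF-consistent", {
  cfg <- tiny_net_config()
  params <- ctprog:::svn_init_params(cfg)
  packs <- small_packs()
  p <- packs[[1]]
  s1 <- survnet_forward(p, cfg, params)
  expect_identical(s1$score, survnet_forward(p, cfg, params)$score)
  expect_s3_class(s1, "risk_score")
  # permute slices within a timepoint: mean embedding unchanged
  p2 <- p
  p2$images[["liver_baseline"]] <- p$images[["liver_baseline"]][c(3, 1, 2)]
  p2$images[["lung_followup"]] <- p$images[["lung_followup"]][c(2, 3, 1)]
  expect_equal(survnet_forward(p2, cfg, params)$score, s1$score, tolerance = 1e-12)
  # LOCF pack and physically-identical-followup pack give the same tensor
  co <- small_cohort()
  missing <- which(!vapply(co$volumes, `[[`, TRUE, "followup_chest_present"))
  skip_if(length(missing) == 0, "no missing-chest patient in fixture")
  pm <- packs[[missing[1]]]
  pm_same <- pm
  pm_same$images[["lung_followup"]] <- pm$images[["lung_baseline"]]
  expect_identical(survnet_forward(pm, cfg, params)$score,
                   survnet_forward(pm_same, cfg, params)$score)
})

test_that("forward is equivariant under a liver/lung swap with swapped branch weights", {
  cfg <- tiny_net_config()
  params <- ctprog:::svn_init_params(cfg)
  tens <- fake_tensor(cfg, 3)
  s1 <- ctprog:::svn_forward_tensor(tens, params, cfg)$score
  swapped <- tens
  for (tp in c("baseline", "followup")) {
    swapped[[paste0("liver_", tp)]] <- tens[[paste0("lung_", tp)]]
    swapped[[paste0("lung_", tp)]] <- tens[[paste0("liver_", tp)]]
  }
  params_sw <- params
  for (fld in c("Wx", "Wh", "b")) {
    params_sw[[paste0("lstm_liver_", fld)]] <- params[[paste0("lstm_lung_", fld)]]
    params_sw[[paste0("lstm_lung_", fld)]] <- params[[paste0("lstm_liver_", fld)]]
  }
  h <- cfg$recurrent_hidden
  params_sw$head_W1 <- params$head_W1[c(h + seq_len(h), seq_len(h)), ]
  s2 <- ctprog:::svn_forward_tensor(swapped, params_sw, cfg)$score
  expect_equal(s2, s1, tolerance = 1e-12)
})

test_that("training with lr = 0 returns the initial-parameter scores", {
  packs <- small_packs()
  co <- small_cohort()
  cfg <- tiny_net_config(epochs = 1, learning_rate = 0, augment_p = 0)
  fit <- train_survnet(packs, co$records, cfg)
  init <- ctprog:::svn_init_params(cfg)
  want <- vapply(packs, function(p) survnet_forward(p, cfg, init)$score, 0)
  expect_equal(unname(fit$scores$score), unname(want), tolerance = 1e-12)
})

test_that("full-batch training loss decreases on a small cohort", {
  packs <- small_packs()
  co <- small_cohort()
  cfg <- tiny_net_config(epochs = 8, learning_rate = 3e-4, augment_p = 0,
                         batch_size = 16)
  fit <- train_survnet(packs, co$records, cfg)
  expect_lt(fit$history[8], fit$history[1])
  # rerun is byte-identical (seeded determinism)
  fit2 <- train_survnet(packs, co$records, cfg)
  expect_identical(fit$scores$score, fit2$scores$score)
})

test_that("an ensemble fit averages its members' standardized scores", {
  packs <- small_packs()
  co <- small_cohort()
  cfg <- tiny_net_config(epochs = 2, learning_rate = 3e-4, augment_p = 0,
                         n_models = 2)
  fit <- train_survnet(packs, co$records, cfg)
  expect_length(fit$members, 2)
  z <- vapply(1:2, function(m)
    (fit$members[[m]]$scores$score - fit$score_norms$mean[m]) /
      fit$score_norms$sd[m], numeric(length(packs)))
  expect_equal(fit$scores$score, rowMeans(z), tolerance = 1e-12)
  # members differ (independent seeds) but predict() is deterministic
  expect_false(isTRUE(all.equal(fit$members[[1]]$scores$score,
                                fit$members[[2]]$scores$score)))
  expect_equal(predict_survnet(fit, packs)$score, fit$scores$score,
               tolerance = 1e-12)
})

test_that("training aborts without events", {
  packs <- small_packs()
  rec <- small_cohort()$records
  rec$event <- 0L
  expect_error(train_survnet(packs, rec, tiny_net_config(epochs = 1)), "no events")
})
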