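# Independent loop oracles: every quantity is recomputed with explicit
# scalar loops over batch items, positions and classes, sharing no code
# with the package internals.

oracle_clip <- function(v, eps) pmin(pmax(v, eps), 1 - eps)

# generic cross entropy-family oracle: `term(pt, class0)` gives the
# per-position contribution from the clipped true-class probability and the
# 0-based true class
oracle_ce_family <- function(p, y, term, eps = 1e-6) {
  d <- dim(p); B <- d[1]; C <- d[length(d)]
  P <- matrix(p, ncol = C); G <- matrix(y, ncol = C)
  npos <- nrow(P) / B
  per <- numeric(B)
  for (b in seq_len(B)) {
    tot <- 0
    for (pos in seq_len(npos)) {
      r <- b + B * (pos - 1)
      cl <- which(G[r, ] == 1)
      tot <- tot + term(oracle_clip(P[r, cl], eps), cl - 1L)
    }
    per[b] <- tot / npos
  }
  per
}

# generic Tversky-family oracle: per item, sum over `cls` (1-based) of
# (1 - TI_c)^(q_c) with TI from soft counts accumulated position by position
oracle_region_family <- function(p, y, alpha, beta, qs, cls, eps = 1e-6) {
  d <- dim(p); B <- d[1]; C <- d[length(d)]
  P <- matrix(p, ncol = C); G <- matrix(y, ncol = C)
  npos <- nrow(P) / B
  per <- numeric(B)
  for (b in seq_len(B)) {
    tot <- 0
    for (cl in cls) {
      tp <- 0; fp <- 0; fn <- 0
      for (pos in seq_len(npos)) {
        r <- b + B * (pos - 1)
        pv <- oracle_clip(P[r, cl], eps); gv <- G[r, cl]
        tp <- tp + pv * gv
        fp <- fp + pv * (1 - gv)
        fn <- fn + (1 - pv) * gv
      }
      ti <- (tp + eps) / (tp + alpha * fp + beta * fn + eps)
      tot <- tot + (1 - ti)^qs[cl]
    }
    per[b] <- tot
  }
  per
}

# per-item oracle values for every loss in the registry, as named list of
# per-item vectors; settings follow the conventional defaults used in the
# package tests
oracle_all_losses <- function(p, y, eps = 1e-6) {
  C <- dim(p)[length(dim(p))]
  delta <- 0.6; gam <- 0.5
  w_delta <- function(cl) if (cl == 0) 1 - delta else delta
  ce <- oracle_ce_family(p, y, function(pt, cl) -log(pt), eps)
  focal <- oracle_ce_family(p, y, function(pt, cl) {
    a <- if (cl == 0) 0.75 else 0.25
    a * (1 - pt)^2 * (-log(pt))
  }, eps)
  mf <- oracle_ce_family(p, y, function(pt, cl) {
    w_delta(cl) * (1 - pt)^gam * (-log(pt))
  }, eps)
  maf <- oracle_ce_family(p, y, function(pt, cl) {
    if (cl == 1) delta * (-log(pt))
    else (1 - delta) * (1 - pt)^gam * (-log(pt))
  }, eps)
  allc <- seq_len(C)
  dice <- oracle_region_family(p, y, 0.5, 0.5, rep(1, C), allc, eps)
  tv <- oracle_region_family(p, y, 0.3, 0.7, rep(1, C), allc, eps)
  ftv <- oracle_region_family(p, y, 0.3, 0.7, rep(1 / (4 / 3), C), allc, eps)
  mft <- oracle_region_family(p, y, delta, 1 - delta, rep(1 - gam, C), allc, eps)
  maft <- oracle_region_family(p, y, delta, 1 - delta,
                               ifelse(seq_len(C) - 1L == 1L, 1 - gam, 1),
                               allc, eps)
  mce <- oracle_ce_family(p, y, function(pt, cl) {
    (if (cl == 0) 0.5 else 0.5) * (-log(pt))
  }, eps)
  fg_dice_score <- 1 - oracle_region_family(p, y, 0.5, 0.5, rep(1, C),
                                            seq(2, C), eps) / (C - 1)
  combo <- 0.5 * mce - 0.5 * fg_dice_score
  hybrid <- 0.5 * focal + 0.5 * ftv
  uf_sym <- 0.5 * mf + 0.5 * mft
  uf_asym <- 0.5 * maf + 0.5 * maft
  list(cross_entropy = ce, focal = focal, modified_focal = mf,
       modified_asymmetric_focal = maf, dice = dice, tversky = tv,
       focal_tversky = ftv, modified_focal_tversky = mft,
       modified_asymmetric_focal_tversky = maft, combo = combo,
       hybrid_focal = hybrid, unified_focal_sym = uf_sym,
       unified_focal_asym = uf_asym)
}

# matching package-side specs for oracle_all_losses
registry_specs <- function() {
  list(cross_entropy = seg_loss("cross_entropy"),
       focal = seg_loss("focal", alpha = 0.25, gamma = 2),
       modified_focal = seg_loss("modified_focal", delta = 0.6, gamma = 0.5),
       modified_asymmetric_focal =
         seg_loss("modified_asymmetric_focal", delta = 0.6, gamma = 0.5),
       dice = seg_loss("dice"),
       tversky = seg_loss("tversky", alpha = 0.3, beta = 0.7),
       focal_tversky = seg_loss("focal_tversky", alpha = 0.3, beta = 0.7,
                                gamma = 4 / 3),
       modified_focal_tversky =
         seg_loss("modified_focal_tversky", delta = 0.6, gamma = 0.5),
       modified_asymmetric_focal_tversky =
         seg_loss("modified_asymmetric_focal_tversky", delta = 0.6,
                  gamma = 0.5),
       combo = seg_loss("combo", combo_alpha = 0.5, beta = 0.5),
       hybrid_focal = seg_loss("hybrid_focal", lambda = 0.5),
       unified_focal_sym = seg_loss("unified_focal", lambda = 0.5,
                                    delta = 0.6, gamma = 0.5),
       unified_focal_asym = seg_loss("unified_focal", variant = "asymmetric",
                                     lambda = 0.5, delta = 0.6, gamma = 0.5))
}

# hard-metric oracle from two label masks of one image (vectors), per class
oracle_hard_metrics <- function(pred, truth, num_classes) {
  out <- NULL
  for (cl in seq_len(num_classes) - 1L) {
    tp <- sum(pred == cl & truth == cl)
    fp <- sum(pred == cl & truth != cl)
    fn <- sum(pred != cl & truth == cl)
    ratio <- function(n, d) if (d > 0) n / d else NA_real_
    out <- rbind(out, data.frame(
      class = cl,
      dsc = ratio(2 * tp, 2 * tp + fp + fn),
      iou = ratio(tp, tp + fp + fn),
      recall = ratio(tp, tp + fn),
      precision = ratio(tp, tp + fp)))
  }
  out
}

# the shared 16-position imbalanced fixture: 4 foreground positions of 16,
# foreground probability 0.5 everywhere (soft counts tp=2, fp=6, fn=2)
fixture_16 <- function() {
  lab <- array(0L, dim = c(1, 4, 4)); lab[1, 1:2, 1:2] <- 1L
  y <- one_hot_encode(lab, 2)
  p <- array(0.5, dim = c(1, 4, 4, 2))
  list(p = p, y = y, labels = lab)
}

# finite-difference gradient of a loss spec w.r.t. every entry of p
fd_gradient <- function(spec, p, y, h = 1e-5) {
  g <- array(0, dim = dim(p))
  for (i in seq_along(p)) {
    pp <- p; pp[i] <- pp[i] + h
    pm <- p; pm[i] <- pm[i] - h
    g[i] <- (compute_loss(spec, pp, y)$value -
               compute_loss(spec, pm, y)$value) / (2 * h)
  }
  g
}
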