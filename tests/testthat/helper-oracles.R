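# Independent oracles and tiny fixtures used across the suite. Everything
# here is deliberately written with a different algorithmic route than the
# package implementation it checks.

# handcrafted 3-sample, 1-stimulus session
tiny_session <- function() {
  session_log(
    subject_id = "tiny", group = "typical", sample_rate_hz = 144,
    gaze = data.frame(t = c(0, 7, 14), x = c(0.5, 0.52, 0.54),
                      y = c(0.5, 0.49, 0.48)),
    stimuli = data.frame(trial_id = 1L, onset = 0, offset = 700,
                         location = 4L, cx = 0.5, cy = 0.5, kind = "go"),
    responses = data.frame(t = 350)
  )
}

# build a session from bare vectors with a uniform time base
make_session <- function(x, y, stimuli, presses = numeric(), rate = 144,
                         group = "typical", subject_id = "s") {
  n <- length(x)
  session_log(
    subject_id = subject_id, group = group, sample_rate_hz = rate,
    gaze = data.frame(t = (seq_len(n) - 1) * 1000 / rate, x = x, y = y),
    stimuli = stimuli,
    responses = data.frame(t = presses)
  )
}

one_go_stimulus <- function(onset = 0, offset = 700, cx = 0.5, cy = 0.5,
                            kind = "go") {
  data.frame(trial_id = 1L, onset = onset, offset = offset, location = 4L,
             cx = cx, cy = cy, kind = kind)
}

# exact AR(2) generator, independent of fit_ar
ar2_gen <- function(n, alpha, th1, th2, sd = 0, y0 = 0.9, y1 = 0.7) {
  y <- numeric(n)
  y[1] <- y0
  y[2] <- y1
  for (t in 3:n) {
    y[t] <- alpha + th1 * y[t - 1] + th2 * y[t - 2] + rnorm(1, 0, sd)
  }
  y
}

# brute-force sample entropy: explicit template extraction and pairwise
# Chebyshev comparison over all (i, j) template pairs
sampen_oracle <- function(x, m, r) {
  n <- length(x)
  nt <- n - m
  templates_m <- lapply(seq_len(nt), function(i) x[i:(i + m - 1)])
  templates_m1 <- lapply(seq_len(nt), function(i) x[i:(i + m)])
  A <- 0
  B <- 0
  for (i in seq_len(nt - 1)) {
    for (j in (i + 1):nt) {
      if (max(abs(templates_m[[i]] - templates_m[[j]])) <= r) {
        B <- B + 1
        if (max(abs(templates_m1[[i]] - templates_m1[[j]])) <= r) A <- A + 1
      }
    }
  }
  if (B == 0 || A == 0) return(NA_real_)
  -log(A / B)
}

# exhaustive step-up check: scan every prefix of the sorted p-values
bh_oracle <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  kstar <- 0
  for (k in seq_len(m)) if (ps[k] <= k * q / m) kstar <- k
  flags <- rep(FALSE, m)
  if (kstar > 0) flags <- p <= ps[kstar]
  flags
}

# convex hull area via Andrew's monotone chain + shoelace (no chull())
hull_area_oracle <- function(x, y) {
  pts <- unique(data.frame(x = x, y = y))
  pts <- pts[order(pts$x, pts$y), ]
  n <- nrow(pts)
  if (n < 3) return(0)
  cross <- function(o, a, b) {
    (a$x - o$x) * (b$y - o$y) - (a$y - o$y) * (b$x - o$x)
  }
  build <- function(idx) {
    h <- integer(0)
    for (i in idx) {
      while (length(h) >= 2 &&
             cross(pts[h[length(h) - 1], ], pts[h[length(h)], ],
                   pts[i, ]) <= 0) {
        h <- h[-length(h)]
      }
      h <- c(h, i)
    }
    h
  }
  hull <- c(build(1:n), build(n:1))
  hull <- hull[!duplicated(hull)]
  hx <- pts$x[hull]
  hy <- pts$y[hull]
  abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
}

# 1-nearest-neighbor classifier for the NCA check
knn1 <- function(Xtr, ytr, Xte) {
  apply(as.matrix(Xte), 1, function(r) {
    ytr[which.min(colSums((t(as.matrix(Xtr)) - r)^2))]
  })
}
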