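# Independent brute-force oracles, written as literal loops so they share no
# code path with the implementation they check.

# polyline roughness: literal per-row loop over sampled positions
roughness_oracle <- function(px, n, rule = "cover") {
  l <- ncol(px)
  s <- floor(l / n)
  n_actual <- if (rule == "cover") {
    if (l %% s == 0) l / s else ceiling(l / s)
  } else {
    n
  }
  rows <- numeric(nrow(px))
  for (j in seq_len(nrow(px))) {
    total <- 0
    for (i in seq_len(n_actual - 1)) {
      dI <- px[j, s * i + 1] - px[j, s * (i - 1) + 1]
      total <- total + sqrt(dI^2 + s^2)
    }
    dI_last <- px[j, l] - px[j, s * (n_actual - 1) + 1]
    total <- total + sqrt(dI_last^2 + (l - s * (n_actual - 1))^2)
    rows[j] <- total / l
  }
  mean(rows)
}

# tailing factor: separate literal outward scan + interpolation
tailing_oracle <- function(counts, f = 0.02) {
  H <- max(counts)
  apex <- which(counts == H)[1] - 1    # lowest-brightness mode, 0-based
  cross <- function(level, dir) {
    i <- apex
    repeat {
      nxt <- i + dir
      if (nxt < 0 || nxt > 255) return(if (dir < 0) 0 else 255)
      if (counts[nxt + 1] < level) break
      i <- nxt
    }
    frac <- (counts[i + 1] - level) / (counts[i + 1] - counts[i + dir + 1])
    i + dir * frac
  }
  lead5 <- cross(H / 2, -1); lag5 <- cross(H / 2, +1)
  bins <- ceiling(lead5):floor(lag5)
  IHbar <- sum(bins * counts[bins + 1]) / sum(counts[bins + 1])
  Ih <- if (abs(IHbar - apex) <= 3) apex else IHbar
  leadf <- cross(f * H, -1); lagf <- cross(f * H, +1)
  (lagf - leadf) / (2 * (Ih - leadf))
}

# 1-D kNN majority vote, nearest-neighbour tie-break
knn_oracle <- function(train_tf, train_grade, k, q) {
  ord <- order(abs(train_tf - q))
  nb <- train_grade[ord[1:k]]
  votes <- table(nb)
  top <- names(votes)[votes == max(votes)]
  if (length(top) == 1) top else nb[which(nb %in% top)[1]]
}

# brightness_histogram object from a raw 256-count vector (lowest-mode apex)
hist_from_counts <- function(counts) {
  stopifnot(length(counts) == 256)
  structure(
    list(counts = as.numeric(counts), H = max(counts),
         I_H = which(counts == max(counts))[1] - 1L, total = sum(counts)),
    class = "brightness_histogram"
  )
}

# random unimodal-ish histogram: gaussian core plus optional right-tail mass
rand_unimodal_counts <- function() {
  mu <- runif(1, 60, 180)
  core <- round(rnorm(round(runif(1, 2000, 8000)), mu, runif(1, 4, 15)))
  tail <- round(runif(round(runif(1, 0, 1500)), mu, min(mu + 80, 250)))
  tabulate(pmin(pmax(c(core, tail), 0), 255) + 1L, nbins = 256L)
}

rand_roi <- function(h = 4, w = NULL) {
  if (is.null(w)) w <- sample(20:60, 1)
  matrix(runif(h * w, 0, 255), h, w)
}

# symmetric triangular histogram centred at `centre`
triangle_counts <- function(centre = 120, half_width = 40, peak = 1000) {
  counts <- numeric(256)
  for (i in 0:255) {
    v <- peak * (1 - abs(i - centre) / half_width)
    counts[i + 1] <- max(0, round(v))
  }
  counts
}
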