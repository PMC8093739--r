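# Independent brute-force oracles, deliberately written as plain exhaustive
# scans so they share no code path with the package implementations.

# Resident events by exhaustive lookback scan (switch_count fixed at 2):
# a single current station; a detection at another station closes the
# current occupancy when a chained partner at that same station exists
# strictly after the last current-station detection. Restated independently
# of the package's forward state machine.
oracle_resident_events <- function(dets, timeout = 3600) {
  res <- list()
  emit <- function(tag, d, members) {
    if (length(members) >= 2) {
      res[[length(res) + 1]] <<- data.frame(
        tag_id = tag, receiver_id = d$receiver_id[members[1]],
        start = d$timestamp[members[1]],
        end = d$timestamp[members[length(members)]],
        n_detections = length(members))
    }
  }
  for (tag in unique(dets$tag_id)) {
    d <- dets[dets$tag_id == tag, , drop = FALSE]
    d <- d[order(d$timestamp), , drop = FALSE]
    tt <- as.numeric(d$timestamp)
    rr <- d$receiver_id
    n <- length(tt)
    members <- 1L
    for (i in seq_len(n)[-1]) {
      lastm <- members[length(members)]
      if (rr[i] == rr[lastm]) {
        if (tt[i] - tt[lastm] <= timeout) {
          members <- c(members, i)
        } else {
          emit(tag, d, members)
          members <- i
        }
      } else {
        # chained partner at station rr[i] after the last member?
        k <- which(rr == rr[i])
        k <- k[k > lastm & k < i & tt[i] - tt[k] <= timeout]
        if (length(k)) {
          emit(tag, d, members)
          # new occupancy = backward timeout chain at this station
          chain <- i
          repeat {
            prev <- which(rr == rr[i])
            prev <- prev[prev > lastm & prev < chain[1] &
                           tt[chain[1]] - tt[prev] <= timeout]
            if (!length(prev)) break
            chain <- c(max(prev), chain)
          }
          members <- chain
        }
      }
    }
    emit(tag, d, members)
  }
  if (!length(res)) {
    return(data.frame(tag_id = character(), receiver_id = character(),
                      start = as.POSIXct(character(), tz = "UTC"),
                      end = as.POSIXct(character(), tz = "UTC"),
                      n_detections = integer()))
  }
  out <- do.call(rbind, res)
  out <- out[order(out$tag_id, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# AUC as the raw fraction of concordant pairs (ties one half), by explicit
# double loop over all positive/negative pairs.
oracle_auc <- function(y, score) {
  pos <- score[y == 1]
  neg <- score[y == 0]
  if (!length(pos) || !length(neg)) return(NA_real_)
  tot <- 0
  for (p in pos) {
    tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  }
  tot / (length(pos) * length(neg))
}

# Exhaustive best least-squares split of (x matrix, residual r): tries every
# midpoint of every predictor, minimum leaf size min_obs, and returns the
# (var, split, improvement) with the tie-break lowest var then lowest split.
oracle_best_split <- function(X, r, min_obs = 1) {
  n <- nrow(X)
  sse <- function(v) if (length(v)) sum((v - mean(v))^2) else 0
  parent_sse <- sse(r)
  best <- list(var = NA, split = NA, improve = 0)
  for (j in seq_len(ncol(X))) {
    xs <- sort(unique(X[, j]))
    if (length(xs) < 2) next
    mids <- (xs[-1] + xs[-length(xs)]) / 2
    for (s in mids) {
      left <- X[, j] <= s
      if (sum(left) < min_obs || sum(!left) < min_obs) next
      imp <- parent_sse - sse(r[left]) - sse(r[!left])
      if (imp > best$improve + 1e-12) {
        best <- list(var = j, split = s, improve = imp)
      }
    }
  }
  best
}

# Direct centered running-median despike along a vector (edge windows
# shrink to the largest odd centred window, leaving the outermost values
# untouched), re-stated independently of the package implementation.
oracle_despike_column <- function(x, window = 3, max_dev = 1) {
  h <- (window - 1) / 2
  out <- x
  for (i in seq_along(x)) {
    hi <- min(h, i - 1, length(x) - i)
    win <- x[(i - hi):(i + hi)]
    m <- median(win)
    if (abs(x[i] - m) > max_dev) out[i] <- m
  }
  out
}

# Mean binomial deviance restated from the formula.
oracle_deviance <- function(y, p) {
  p <- pmin(pmax(p, 1e-8), 1 - 1e-8)
  -2 * mean(y * log(p) + (1 - y) * log(1 - p))
}

# Random detection log for property tests: n detections of one tag over a
# few receivers with mixed gap scales.
random_log <- function(n, n_receivers = 3, seed = 1) {
  set.seed(seed)
  gaps <- sample(c(30, 120, 1800, 4000, 50000), n, replace = TRUE,
                 prob = c(0.4, 0.25, 0.15, 0.15, 0.05))
  data.frame(
    timestamp = as.POSIXct("2020-01-01", tz = "UTC") + cumsum(gaps),
    tag_id = "T1",
    receiver_id = sample(paste0("R", seq_len(n_receivers)), n, replace = TRUE),
    stringsAsFactors = FALSE)
}
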