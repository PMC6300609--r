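# Contiguous displacement segments of one track, with frame bookkeeping.
# Returns list of (disp, frames) where frames has length(disp) + 1.
track_segments <- function(tr) {
  if (nrow(tr) < 2) return(list())
  lag <- diff(tr$frame)
  ds <- diff(tr$s_nm)
  runs <- rle(lag == 1)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  out <- list()
  for (k in seq_along(runs$values)) {
    if (runs$values[k]) {
      out[[length(out) + 1]] <- list(
        disp = ds[starts[k]:ends[k]],
        frames = tr$frame[starts[k]:(ends[k] + 1)]
      )
    }
  }
  out
}

#' Decode per-frame diffusion states
#'
#' Assigns every frame of every track its most probable hidden state. By
#' default the per-displacement posterior marginals from the forward-backward
#' recursion are used (so state fractions match expected occupancies); Viterbi
#' decoding is available for the single most probable path. Each frame takes
#' the state of the displacement that starts there; the last frame of a
#' segment repeats its final displacement's state.
#'
#' @param model A fitted [fit_hmm()] model.
#' @param tracks A [scan_tracks()] table with the model's frame interval.
#' @param method `"posterior"` (default) or `"viterbi"`.
#' @param return_posterior If TRUE, append the posterior marginal columns
#'   `post_1..post_K` (posterior method only).
#' @return A `state_path` data frame: `track_id`, `frame`, `state` (1..K,
#'   ascending diffusion). Tracks shorter than 2 frames contribute no rows.
#' @export
decode_states <- function(model, tracks, method = c("posterior", "viterbi"),
                          return_posterior = FALSE) {
  stopifnot(inherits(model, "diffusion_hmm"), inherits(tracks, "scan_tracks"))
  method <- match.arg(method)
  if (abs(frame_interval(tracks) - model$frame_interval) > 1e-12) {
    stop("tracks and model have different frame intervals")
  }
  K <- model$K
  v <- 2 * model$D * .NM2_PER_UM2 * model$frame_interval + 2 * model$sigma_loc^2
  v <- pmax(v, 1e-12)
  rows <- list()
  for (id in unique(tracks$track_id)) {
    tr <- tracks[tracks$track_id == id, ]
    seg_rows <- list()
    for (seg in track_segments(tr)) {
      m <- length(seg$disp)
      if (method == "posterior") {
        e <- hmm_estep_cpp(seg$disp, m, v, model$pi, model$A, TRUE)
        g <- matrix(e$gamma, nrow = m, ncol = K)
        st <- max.col(g, ties.method = "first")
      } else {
        st <- viterbi_path(seg$disp, v, model$pi, model$A)
        g <- NULL
      }
      df <- data.frame(track_id = id,
                       frame = seg$frames,
                       state = c(st, st[m]))
      if (return_posterior && !is.null(g)) {
        gp <- rbind(g, g[m, , drop = FALSE])
        colnames(gp) <- paste0("post_", seq_len(K))
        df <- cbind(df, gp)
      }
      seg_rows[[length(seg_rows) + 1]] <- df
    }
    if (!length(seg_rows)) next
    df <- do.call(rbind, seg_rows)
    # a frame isolated between two blink gaps belongs to no contiguous
    # segment; give it the state of the nearest decoded frame
    orphan <- setdiff(tr$frame, df$frame)
    if (length(orphan)) {
      near <- vapply(orphan, function(f) which.min(abs(df$frame - f)), 0L)
      extra <- df[near, , drop = FALSE]
      extra$frame <- orphan
      df <- rbind(df, extra)
      df <- df[order(df$frame), , drop = FALSE]
    }
    rows[[length(rows) + 1]] <- df
  }
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(track_id = integer(0), frame = integer(0), state = integer(0))
  }
  rownames(out) <- NULL
  structure(out, class = c("state_path", "data.frame"), K = K)
}

# log-space Viterbi for one displacement sequence
viterbi_path <- function(obs, v, pi0, A) {
  K <- length(v)
  n <- length(obs)
  lb <- sapply(seq_len(K), function(k) stats::dnorm(obs, 0, sqrt(v[k]), log = TRUE))
  lb <- matrix(lb, nrow = n)
  lA <- log(pmax(A, 1e-300))
  delta <- matrix(-Inf, n, K)
  psi <- matrix(0L, n, K)
  delta[1, ] <- log(pmax(pi0, 1e-300)) + lb[1, ]
  if (n > 1) {
    for (t in 2:n) {
      for (k in seq_len(K)) {
        cand <- delta[t - 1, ] + lA[, k]
        psi[t, k] <- which.max(cand)
        delta[t, k] <- cand[psi[t, k]] + lb[t, k]
      }
    }
  }
  st <- integer(n)
  st[n] <- which.max(delta[n, ])
  if (n > 1) for (t in (n - 1):1) st[t] <- psi[t + 1, st[t + 1]]
  st
}

#' Map hidden states to scanning-mode labels
#'
#' States are ordered by ascending diffusion coefficient, so for a 3-state
#' model state 1 maps to interrogation, 2 to sliding, 3 to hopping.
#'
#' @param states Integer state vector (1..K).
#' @param K State count (default 3).
#' @return Factor with [mode_levels()] levels.
#' @export
states_to_modes <- function(states, K = 3) {
  if (K != 3) stop("mode mapping is defined for 3-state models")
  factor(mode_levels()[states], levels = mode_levels())
}

#' Recompute state statistics on the diffusion-assigned frames
#'
#' For a like-for-like comparison with the activation-energy classification,
#' restricts the decoded state path to the frames that also carry an
#' instantaneous diffusion value (the sliding window leaves the last four
#' frames of every track unassigned) and recomputes per-state occupancy and
#' mean diffusion.
#'
#' @param paths A `state_path` from [decode_states()].
#' @param series The matching `diffusion_series`.
#' @return Data frame with one row per state: `state`, `occupancy`, `mean_D`,
#'   `sem_D`, `n`.
#' @export
trim_and_recompute <- function(paths, series) {
  if (!all(unique(series$track_id) %in% unique(paths$track_id))) {
    stop("paths and series cover different track sets")
  }
  key_p <- paste(paths$track_id, paths$frame)
  key_s <- paste(series$track_id, series$frame)
  idx <- match(key_s, key_p)
  if (any(is.na(idx))) stop("series frames missing from the decoded paths")
  st <- paths$state[idx]
  d <- series$D_inst_um2_s
  K <- attr(paths, "K")
  if (is.null(K)) K <- max(paths$state)
  n <- tabulate(st, nbins = K)
  mean_d <- vapply(seq_len(K), function(k) {
    if (n[k]) mean(d[st == k]) else NA_real_
  }, numeric(1))
  sem_d <- vapply(seq_len(K), function(k) {
    if (n[k] > 1) stats::sd(d[st == k]) / sqrt(n[k]) else 0
  }, numeric(1))
  data.frame(state = seq_len(K), occupancy = n / length(st),
             mean_D = mean_d, sem_D = sem_d, n = n)
}

#' Frame-level agreement between two classifications
#'
#' @param modesA,modesB Equal-length aligned label vectors (factors or
#'   integers).
#' @return Fraction of frames with identical labels, in [0, 1].
#' @export
agreement <- function(modesA, modesB) {
  if (length(modesA) != length(modesB)) {
    stop("label vectors have different lengths")
  }
  if (!length(modesA)) stop("empty label vectors")
  mean(as.character(modesA) == as.character(modesB))
}

#' Empirical transition matrix of decoded paths
#'
#' Row-normalized counts of state pairs in consecutive frames, pooled over
#' tracks (never across track boundaries or blink gaps).
#'
#' @param paths A `state_path`.
#' @param K State count (default: taken from `paths`).
#' @return K x K matrix with rows summing to 1 (rows never visited are
#'   uniform NA).
#' @export
transition_matrix <- function(paths, K = attr(paths, "K")) {
  if (is.null(K)) K <- max(paths$state)
  counts <- matrix(0, K, K)
  for (id in unique(paths$track_id)) {
    p <- paths[paths$track_id == id, ]
    ok <- diff(p$frame) == 1
    a <- p$state[-nrow(p)][ok]
    b <- p$state[-1][ok]
    for (i in seq_along(a)) counts[a[i], b[i]] <- counts[a[i], b[i]] + 1
  }
  if (sum(counts) < 1) stop("no transitions observed")
  rs <- rowSums(counts)
  out <- counts / ifelse(rs > 0, rs, NA)
  out
}

#' Memory diagnostic for sojourns through a state
#'
#' Tests whether exits from a state remember the entry: over all maximal
#' sojourns in state `via` that are entered from state s and exited to state
#' e (both different from `via`), compares the observed odds of returning
#' (e = s) with the memoryless expectation computed from the empirical entry
#' and exit marginals. A ratio of 1 indicates Markovian switching; a ratio of
#' 2 means returning is twice as likely as memoryless switching would make it.
#'
#' @param paths A `state_path`.
#' @param via State index whose sojourns are examined (default 2, the sliding
#'   state of a 3-state model).
#' @return List of class `memory_stat`: `ratio`, `p_return`, `p_memoryless`,
#'   `n_sojourns`. `ratio` is `NA` when no qualifying sojourn exists.
#' @export
triplet_memory <- function(paths, via = 2) {
  entries <- integer(0)
  exits <- integer(0)
  for (id in unique(paths$track_id)) {
    st <- paths$state[paths$track_id == id]
    r <- rle(st)
    k <- length(r$values)
    if (k < 3) next
    for (j in 2:(k - 1)) {
      if (r$values[j] == via && r$values[j - 1] != via && r$values[j + 1] != via) {
        entries <- c(entries, r$values[j - 1])
        exits <- c(exits, r$values[j + 1])
      }
    }
  }
  n <- length(entries)
  if (n == 0) {
    return(structure(list(ratio = NA_real_, p_return = NA_real_,
                          p_memoryless = NA_real_, n_sojourns = 0L),
                     class = "memory_stat"))
  }
  p_ret <- mean(exits == entries)
  p_in <- table(factor(entries, levels = sort(unique(c(entries, exits))))) / n
  p_out <- table(factor(exits, levels = sort(unique(c(entries, exits))))) / n
  p0 <- sum(as.numeric(p_in) * as.numeric(p_out))
  odds <- function(p) p / (1 - p)
  ratio <- if (p_ret %in% c(0, 1) || p0 %in% c(0, 1)) {
    if (p_ret > p0) Inf else 0
  } else {
    odds(p_ret) / odds(p0)
  }
  structure(list(ratio = ratio, p_return = p_ret, p_memoryless = p0,
                 n_sojourns = n), class = "memory_stat")
}

#' @export
print.memory_stat <- function(x, ...) {
  cat(sprintf(
    "return-memory odds ratio %.3f (P(return) %.3f vs memoryless %.3f; %d sojourns)\n",
    x$ratio, x$p_return, x$p_memoryless, x$n_sojourns))
  invisible(x)
}

#' Reducibility of a transition matrix
#'
#' Zeroes out transition probabilities below `eps` and tests whether the
#' surviving directed state graph is strongly connected. A matrix that is
#' reducible at `eps` but irreducible at `eps / 10` is reported as nearly
#' reducible (its connectivity hinges on rare transitions).
#'
#' @param A Row-stochastic K x K matrix.
#' @param eps Probability floor below which a transition is treated as absent.
#' @return One of `"irreducible"`, `"nearly_reducible"`, `"reducible"`.
#' @export
reducibility <- function(A, eps = 1e-3) {
  A <- as.matrix(A)
  if (nrow(A) != ncol(A)) stop("transition matrix must be square")
  if (any(abs(rowSums(A) - 1) > 1e-6)) stop("rows must sum to 1")
  strongly_connected <- function(thr) {
    B <- (A >= thr) | diag(nrow(A)) > 0
    R <- B
    for (i in seq_len(nrow(A) - 1)) R <- (R %*% B) > 0 | R
    all(R)
  }
  if (strongly_connected(eps)) return("irreducible")
  if (strongly_connected(eps / 10)) return("nearly_reducible")
  "reducible"
}

#' Frequency of switching into a state per 1000 bp traversed
#'
#' Counts entries into `target` from any other state along the decoded paths
#' and normalizes by the cumulative distance travelled along the DNA
#' (sum of |displacement| over all steps), converted to base pairs.
#'
#' @param paths A `state_path`.
#' @param tracks The matching [scan_tracks()] table.
#' @param target State index entered (default 1, interrogation).
#' @param bp_nm Helical rise, nm per bp.
#' @return Switching events per 1000 bp, or `NA` if no DNA was traversed.
#' @export
switch_frequency <- function(paths, tracks, target = 1, bp_nm = 0.34) {
  entries <- 0L
  for (id in unique(paths$track_id)) {
    st <- paths$state[paths$track_id == id]
    if (length(st) < 2) next
    entries <- entries + sum(st[-1] == target & st[-length(st)] != target)
  }
  travel_nm <- 0
  for (id in unique(tracks$track_id)) {
    s <- tracks$s_nm[tracks$track_id == id]
    if (length(s) > 1) travel_nm <- travel_nm + sum(abs(diff(s)))
  }
  if (travel_nm <= 0) return(NA_real_)
  entries / (travel_nm / bp_nm) * 1000
}
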