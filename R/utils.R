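# shared internal helpers

# trailing-window running maximum: y[i] = max(x[max(1, i-w+1) .. i]).
# O(n) two-pass block decomposition (prefix cummax within blocks + suffix
# cummax within blocks), vectorised; w-sample blocks.
rolling_max_trailing <- function(x, w) {
  n <- length(x)
  w <- as.integer(w)
  if (w <= 1L) return(x)
  if (w >= n) return(cummax(x))
  nb <- ceiling(n / w)
  xp <- c(x, rep(-Inf, nb * w - n))
  m <- matrix(xp, nrow = w, ncol = nb)
  pref <- apply(m, 2L, cummax)                       # prefix max within block
  suff <- apply(m[w:1, , drop = FALSE], 2L, cummax)[w:1, , drop = FALSE]
  pref <- as.vector(pref)[seq_len(n)]
  suff <- as.vector(suff)[seq_len(n)]
  i <- seq_len(n)
  start <- i - w + 1L
  out <- pref
  has_tail <- start >= 1L
  out[has_tail] <- pmax(suff[start[has_tail]], pref[i[has_tail]])
  out[!has_tail] <- pref[i[!has_tail]]   # window truncated at signal start
  out
}

# indices of strict-left / weak-right local maxima (interior points only)
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  i <- 2:(n - 1L)
  i[x[i] > x[i - 1L] & x[i] >= x[i + 1L]]
}

# greedy one-to-one matching of two ascending index vectors within a
# tolerance (in samples). Pairs are taken in order of increasing distance.
# Returns a data.frame with one row per reference index: the matched
# detected index (NA if unmatched) and the position of that detection.
match_events <- function(detected, reference, tol_samples) {
  nr <- length(reference)
  if (nr == 0L) {
    return(data.frame(reference = integer(0), detected = integer(0),
                      det_pos = integer(0)))
  }
  cand_ref <- integer(0); cand_det <- integer(0); cand_d <- numeric(0)
  if (length(detected) > 0L) {
    for (j in seq_len(nr)) {
      d <- abs(detected - reference[j])
      ok <- which(d <= tol_samples)
      if (length(ok) > 0L) {
        cand_ref <- c(cand_ref, rep(j, length(ok)))
        cand_det <- c(cand_det, ok)
        cand_d <- c(cand_d, d[ok])
      }
    }
  }
  match_det <- rep(NA_integer_, nr)
  if (length(cand_d) > 0L) {
    used_det <- logical(length(detected))
    for (k in order(cand_d, cand_ref)) {
      j <- cand_ref[k]; i <- cand_det[k]
      if (is.na(match_det[j]) && !used_det[i]) {
        match_det[j] <- i
        used_det[i] <- TRUE
      }
    }
  }
  data.frame(reference = reference,
             detected = ifelse(is.na(match_det), NA_integer_,
                               detected[match_det]),
             det_pos = match_det)
}

# little-endian unsigned 16-bit encode/decode on raw vectors
u16_to_raw <- function(x) {
  x <- as.integer(x)
  if (any(x < 0L | x > 65535L)) stop("u16 value out of range", call. = FALSE)
  as.raw(c(rbind(x %% 256L, x %/% 256L)))
}

raw_to_u16 <- function(r) {
  stopifnot(length(r) %% 2L == 0L)
  v <- as.integer(r)
  v[c(TRUE, FALSE)] + 256L * v[c(FALSE, TRUE)]
}
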