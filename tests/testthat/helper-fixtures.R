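# fixtures built in code: synthetic PQRST windows, random quantized
# beats, and tiny WFDB records written to tempdir at test time.

# one Gaussian-bump PQRST window aligned on the R sample
make_pqrst_window <- function(fs = 360, abnormal = FALSE, adc = TRUE) {
  spec <- window_spec(fs)
  t <- (-spec$n_pre:spec$n_post) / fs
  mu <- c(-0.170, -0.025, 0.000, 0.028, 0.230)
  amp <- c(0.15, -0.12, 1.20, -0.25, 0.35)
  sg <- c(0.025, 0.010, 0.012, 0.010, 0.055)
  if (abnormal) {
    amp[1] <- 0; amp[3] <- amp[3] * 1.3; sg[3] <- sg[3] * 3; amp[5] <- -amp[5]
  }
  w <- rowSums(sapply(1:5, function(j) amp[j] * exp(-(t - mu[j])^2 / (2 * sg[j]^2))))
  if (adc) w <- pmin(1023, pmax(0, round((w + 1.5) / 4 * 1023)))
  w
}

rand_levels <- function(n, A) sample(0:(A - 1L), n, replace = TRUE)

# independent brute-force re-statement of the three saturating
# increment rules, cell by cell
brute_force_train <- function(level_list, A, cap = 10L) {
  n <- length(level_list[[1]])
  cells <- matrix(0L, n, A)
  for (lv in level_list) {
    for (i in seq_len(n)) {
      for (off in c(0L, -1L, 1L)) {
        r <- lv[i] + off
        if (r >= 0L && r <= A - 1L && cells[i, r + 1L] < cap) {
          cells[i, r + 1L] <- cells[i, r + 1L] + 1L
        }
      }
    }
  }
  cells
}

brute_force_ratepm <- function(cells, lv) {
  sum(vapply(seq_along(lv), function(i) cells[i, lv[i] + 1L] > 7L, logical(1)))
}

levels_to_beat <- function(lv, A) {
  structure(list(levels = as.integer(lv), raw_window = as.numeric(lv),
                 A = as.integer(A), r_index = NA_integer_),
            class = "quantized_beat")
}

# --- tiny WFDB record writers (binary files go to tempdir) ---

write_wfdb_fixture <- function(dir, name, channels, fs, fmt = 16L,
                               ann = NULL) {
  nsig <- length(channels)
  nsamp <- length(channels[[1]])
  hea <- c(sprintf("%s %d %g %d", name, nsig, fs, nsamp),
           sprintf("%s.dat %d 200(0) 12 0 0 0 0 ch%d", name, fmt, seq_len(nsig)))
  writeLines(hea, file.path(dir, paste0(name, ".hea")))
  inter <- as.integer(do.call(rbind, lapply(channels, as.integer)))
  dat <- file.path(dir, paste0(name, ".dat"))
  if (fmt == 16L) {
    writeBin(inter, dat, size = 2L, endian = "little")
  } else if (fmt == 212L) {
    if (length(inter) %% 2L == 1L) inter <- c(inter, 0L)
    u <- inter %% 4096L   # 12-bit two's complement
    s1 <- u[c(TRUE, FALSE)]; s2 <- u[c(FALSE, TRUE)]
    b <- as.raw(rbind(s1 %% 256L, s1 %/% 256L + 16L * (s2 %/% 256L),
                      s2 %% 256L))
    writeBin(as.vector(b), dat)
  } else stop("fixture writer: unsupported format")
  if (!is.null(ann)) {
    write_atr_fixture(file.path(dir, paste0(name, ".atr")),
                      ann$time, ann$code)
  }
  file.path(dir, name)
}

# MIT annotation file: u16 words, code in the high 6 bits, time delta in
# the low 10 bits, zero word terminates
write_atr_fixture <- function(path, times, codes) {
  deltas <- diff(c(0L, as.integer(times)))
  stopifnot(all(deltas >= 0L & deltas < 1024L))
  words <- c(as.integer(codes) * 1024L + deltas, 0L)
  writeBin(as.raw(c(rbind(words %% 256L, words %/% 256L))), path)
  invisible(path)
}

# small synthetic record cached per test file
noise_free_config <- function(seed, duration_s = 60, abnormal_rate = 0) {
  synth_config(duration_s = duration_s, seed = seed,
               abnormal_rate = abnormal_rate, white_snr_db = Inf,
               baseline_amp_mv = 0, mains_amp_mv = 0)
}
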