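# Fixture builders shared across test files. Everything is generated in
# code; nothing is read from disk except what the tests themselves write.

# A raw recording built directly from timestamps and (optionally) landmark
# matrices; frames with `valid = FALSE` carry no landmarks.
make_raw_recording <- function(times, valid = rep(TRUE, length(times)),
                               coords = NULL, participant = "P01",
                               group_values = c(condition = "A")) {
  tpl <- as.matrix(face_template()[, c("x", "y")])
  lms <- lapply(seq_along(times), function(i) {
    if (!valid[i]) return(NULL)
    if (is.null(coords)) tpl else coords[[i]]
  })
  structure(
    list(participant_id = participant, group_values = group_values,
         frames = tibble::tibble(time = times, valid = valid,
                                 landmarks = lms),
         source_file = "fixture", parse_log = list()),
    class = "raw_recording"
  )
}

# An aligned recording on a uniform grid with a programmable nose-tip path
# and fixed eye landmarks (known pixel IOD).
make_recording <- function(t_n = 11, rate = 5, nose_path = NULL,
                           scale = 1, shift = c(0, 0),
                           participant = "P01") {
  tpl <- as.matrix(face_template()[, c("x", "y")])
  lm <- array(NA_real_, dim = c(t_n, 68, 2))
  for (i in seq_len(t_n)) {
    frame <- tpl
    if (!is.null(nose_path)) frame[34, ] <- nose_path[i, ]
    lm[i, , 1] <- frame[, 1] * scale + shift[1]
    lm[i, , 2] <- frame[, 2] * scale + shift[2]
  }
  structure(
    list(time = (seq_len(t_n) - 1) / rate, landmarks = lm, emotions = NULL,
         head_movement = NULL, participant_id = participant,
         group_values = c(condition = "A"), rate = rate,
         settings = list()),
    class = "recording"
  )
}

template_iod_px <- function() {
  tpl <- as.matrix(face_template()[, c("x", "y")])
  sqrt(sum((colMeans(tpl[37:42, ]) - colMeans(tpl[43:48, ]))^2))
}

# Brute-force within/between covariance oracle: naive loops over the
# definition, independent of the package's pooled implementation.
brute_covariances <- function(arr) {
  n <- dim(arr)[1]; d <- dim(arr)[2]; t_n <- dim(arr)[3]
  xc <- lapply(seq_len(n), function(i) {
    xi <- matrix(arr[i, , ], nrow = d)
    xi - rowMeans(xi)
  })
  rij <- function(i, j) {
    m <- matrix(0, d, d)
    for (t in seq_len(t_n)) m <- m + xc[[i]][, t] %o% xc[[j]][, t]
    m / (t_n - 1)
  }
  r_w_i <- lapply(seq_len(n), function(i) rij(i, i))
  r_b_i <- lapply(seq_len(n), function(i) {
    m <- matrix(0, d, d)
    for (j in setdiff(seq_len(n), i)) m <- m + (rij(i, j) + rij(j, i)) / 2
    m
  })
  list(R_w = Reduce(`+`, r_w_i), R_b = Reduce(`+`, r_b_i),
       R_w_i = r_w_i, R_b_i = r_b_i)
}

# Independent maximiser of the generalised Rayleigh quotient
# (w' R_b w)/(w' R_wg w): dense direction grid plus Nelder-Mead polish.
rayleigh_max <- function(r_b, r_wg, n_grid = 20000) {
  d <- nrow(r_b)
  quot <- function(w) {
    as.numeric((w %*% r_b %*% w) / (w %*% r_wg %*% w))
  }
  if (d == 2) {
    ang <- seq(0, pi, length.out = n_grid)
    vals <- vapply(ang, function(a) quot(c(cos(a), sin(a))), numeric(1))
    best <- ang[which.max(vals)]
    opt <- stats::optim(best, function(a) -quot(c(cos(a), sin(a))),
                        method = "Brent",
                        lower = best - 0.01, upper = best + 0.01)
    return(-opt$value)
  }
  set.seed(99)
  dirs <- matrix(rnorm(n_grid * d), ncol = d)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  vals <- apply(dirs, 1, quot)
  w0 <- dirs[which.max(vals), ]
  opt <- stats::optim(w0, function(w) -quot(w / sqrt(sum(w^2))),
                      control = list(maxit = 5000, reltol = 1e-12))
  -opt$value
}

# White-noise subjects x samples matrix.
noise_matrix <- function(n, t_n, seed) {
  set.seed(seed)
  matrix(rnorm(n * t_n), nrow = n,
         dimnames = list(sprintf("S%02d", seq_len(n)), NULL))
}
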