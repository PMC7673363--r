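# Shared fixtures built in code.

# noiseless linear-decline window: o2(t) = a + b * t (t in s)
linear_window <- function(a = 8, b = -0.001, t = seq(0, 298, by = 2)) {
  data.frame(time_s = t, o2_mg_l = a + b * t)
}

# regular n-gon of circumradius r as a single-frame trajectory
polygon_frame <- function(n, r, frame = 1) {
  ang <- 2 * pi * (seq_len(n) - 1) / n
  data.frame(frame = frame, fish_id = paste0("f", seq_len(n)),
             x = r * cos(ang), y = r * sin(ang), stringsAsFactors = FALSE)
}

# brute-force mean pairwise distance, double loop (independent oracle)
naive_mean_pairdist <- function(x, y) {
  n <- length(x)
  s <- 0; k <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    s <- s + sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2)
    k <- k + 1
  }
  s / k
}

# brute-force trial cohesion: per-frame naive mean over valid pairs
naive_cohesion <- function(traj) {
  vals <- c()
  for (f in sort(unique(traj$frame))) {
    sub <- traj[traj$frame == f, ]
    ok <- !is.na(sub$x) & !is.na(sub$y)
    if (sum(ok) >= 2) vals <- c(vals, naive_mean_pairdist(sub$x[ok], sub$y[ok]))
  }
  mean(vals)
}

# default chamber used across respirometry tests
test_chamber <- function() chamber_config(75, 5, fish_volume = 1.65)
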