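# Independent brute-force oracles and shared fixtures.
# The oracles enumerate pixel pairs / table cells directly and share no code
# with the implementation.

brute_quantize <- function(block, G) {
  q <- floor(block * G / 256)
  q[q > G - 1] <- G - 1
  q
}

# explicit pair enumeration, symmetric accumulation
brute_glcm <- function(block, d, theta, G) {
  q <- brute_quantize(block, G)
  off <- switch(as.character(theta),
                "0" = c(0, d), "45" = c(-d, d),
                "90" = c(-d, 0), "135" = c(-d, -d))
  P <- matrix(0, G, G)
  for (r in seq_len(nrow(q))) {
    for (cc in seq_len(ncol(q))) {
      r2 <- r + off[1]; c2 <- cc + off[2]
      if (r2 >= 1 && r2 <= nrow(q) && c2 >= 1 && c2 <= ncol(q)) {
        P[q[r, cc] + 1, q[r2, c2] + 1] <- P[q[r, cc] + 1, q[r2, c2] + 1] + 1
        P[q[r2, c2] + 1, q[r, cc] + 1] <- P[q[r2, c2] + 1, q[r, cc] + 1] + 1
      }
    }
  }
  P / sum(P)
}

# direct evaluation of the four statistics by double loops (base-10 entropy)
brute_stats <- function(P) {
  G <- nrow(P)
  asm <- 0; ent <- 0; con <- 0; sij <- 0
  for (i in seq_len(G)) {
    for (j in seq_len(G)) {
      p <- P[i, j]
      asm <- asm + p^2
      if (p > 0) ent <- ent - p * log10(p)
      con <- con + ((i - 1) - (j - 1))^2 * p
      sij <- sij + (i - 1) * (j - 1) * p
    }
  }
  px <- rowSums(P); py <- colSums(P)
  ux <- sum((seq_len(G) - 1) * px); uy <- sum((seq_len(G) - 1) * py)
  sx <- sqrt(sum(((seq_len(G) - 1) - ux)^2 * px))
  sy <- sqrt(sum(((seq_len(G) - 1) - uy)^2 * py))
  cor <- if (sx * sy == 0) 0 else (sij - ux * uy) / (sx * sy)
  c(asm = asm, ent = ent, con = con, cor = cor)
}

# ---- shared fixtures (computed once per test run) --------------------------

.fixture_env <- new.env(parent = emptyenv())

cached_fixture <- function(name, fn) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, fn(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# low-effort tuning settings for tests; tuning quality is not under test
# where these are used
fast_pso <- function(seed = 5) {
  pso_config(swarm_size = 6, iterations = 6, fitness_folds = 3, seed = seed)
}
fast_lo <- function() {
  lo_config(C_step = 0.5, g_step = 0.5, C_halfwidth = 1, g_halfwidth = 1)
}

# high-contrast phantom overrides used where clear class separation is the
# test precondition
high_contrast <- list(lesion_contrast = -70, lesion_texture_std = 25)

fx_phantom_features <- function() {
  cached_fixture("phantom_features", function() {
    ds <- generate_dataset(c(cancer = 10, normal = 14),
                           config_overrides = high_contrast, master_seed = 11)
    phantom_instance_table(ds)
  })
}

fx_classifier <- function() {
  cached_fixture("classifier", function() {
    build_classifier(fx_phantom_features(), pso = fast_pso(), lo = fast_lo(),
                     io = io_config(selection_folds = 3), seed = 3)
  })
}

# synthetic separable instance table in the tidy feature layout
synth_features <- function(n_bags = 10, n_inst = 9, sep = 3, seed = 1,
                           shuffle_labels = FALSE) {
  withr::with_seed(seed, {
    bag_label <- rep(c(1L, -1L), length.out = n_bags)
    if (shuffle_labels) bag_label <- sample(bag_label)
    rows <- lapply(seq_len(n_bags), function(b) {
      bl <- bag_label[b]
      mu <- 0.5 + bl * sep / 10
      tibble::tibble(
        bag_id = sprintf("bag%02d", b),
        bag_label = bl,
        class = if (bl == 1) "cancer" else "normal",
        instance_id = seq_len(n_inst),
        grid_row = 1L, grid_col = seq_len(n_inst),
        label = bl, a_j = 0L, reserved = TRUE,
        asm_mean_d1 = pmin(stats::rnorm(n_inst, mu / 2, 0.05), 0.9),
        ent_mean_d1 = stats::rnorm(n_inst, mu, 0.1),
        con_mean_d1 = stats::rnorm(n_inst, mu * 2, 0.2),
        cor_mean_d1 = stats::rnorm(n_inst, mu / 3, 0.05))
    })
    dplyr::bind_rows(rows)
  })
}
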