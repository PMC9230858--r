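# Shared fixtures and independent oracles.
#
# The connected-component oracles deliberately use a different algorithm
# (iterative minimum-label propagation) from the package's breadth-first
# region growing, so agreement is a real cross-check.

# -- oracles -----------------------------------------------------------------

oracle_components_2d <- function(fg) {
  ny <- nrow(fg); nx <- ncol(fg)
  lab <- matrix(0L, ny, nx)
  lab[fg] <- seq_len(sum(fg))
  repeat {
    P <- matrix(0L, ny + 2L, nx + 2L)
    P[2:(ny + 1L), 2:(nx + 1L)] <- lab
    nb <- list(P[1:ny, 2:(nx + 1L)], P[3:(ny + 2L), 2:(nx + 1L)],
               P[2:(ny + 1L), 1:nx], P[2:(ny + 1L), 3:(nx + 2L)])
    new <- lab
    for (m in nb) {
      cand <- fg & m > 0L & (new == 0L | m < new)
      new[cand] <- m[cand]
    }
    if (identical(new, lab)) break
    lab <- new
  }
  lab
}

oracle_components_3d <- function(fg) {
  d <- dim(fg)
  lab <- array(0L, d)
  lab[fg] <- seq_len(sum(fg))
  repeat {
    P <- array(0L, d + 2L)
    P[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- lab
    i1 <- 2:(d[1] + 1L); i2 <- 2:(d[2] + 1L); i3 <- 2:(d[3] + 1L)
    nb <- list(P[i1 - 1L, i2, i3], P[i1 + 1L, i2, i3],
               P[i1, i2 - 1L, i3], P[i1, i2 + 1L, i3],
               P[i1, i2, i3 - 1L], P[i1, i2, i3 + 1L])
    new <- lab
    for (m in nb) {
      cand <- fg & m > 0L & (new == 0L | m < new)
      new[cand] <- m[cand]
    }
    if (identical(new, lab)) break
    lab <- new
  }
  lab
}

# relabel components by first occurrence over the linear index, so two
# labelings of the same partition become identical arrays
canon_labels <- function(lab) {
  out <- lab
  out[] <- 0L
  seen <- integer(0)
  nz <- which(lab != 0L)
  map <- integer(max(lab, 1L))
  nxt <- 0L
  for (i in nz) {
    v <- lab[i]
    if (map[v] == 0L) { nxt <- nxt + 1L; map[v] <- nxt }
    out[i] <- map[v]
  }
  out
}

sad_oracle <- function(image, template) {
  nu <- nrow(image) - nrow(template) + 1L
  nv <- ncol(image) - ncol(template) + 1L
  m <- matrix(NA_real_, nu, nv)
  for (u in seq_len(nu)) for (v in seq_len(nv))
    m[u, v] <- sum(abs(image[u:(u + nrow(template) - 1L),
                             v:(v + ncol(template) - 1L)] - template))
  m
}

# -- fixtures ----------------------------------------------------------------

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

# compact 12-pair phantom used by most tests (fast to generate and label)
small_spec <- function(...) phantom_spec(ny = 160L, nx = 160L, nz = 56L, ...)

small_phantom <- function() memo("small_phantom", generate_phantom(small_spec()))

small_iip_run <- function() memo("small_iip_run", {
  ph <- small_phantom()
  ts <- generate_template_set(ph)
  win <- apply_window(ph$volume)
  mask <- build_iip_mask(win, ts)
  list(ph = ph, ts = ts, win = win, mask = mask,
       seq = label_sequence(mask))
})

# the reference full-scale phantom run shared by the acceptance checks
default_run <- function() memo("default_run", {
  ph <- generate_phantom(phantom_spec())
  ts <- generate_template_set(ph)
  win <- apply_window(ph$volume)
  mask <- build_iip_mask(win, ts)
  lc <- label_clusters(mask)
  list(ph = ph, ts = ts, win = win, mask = mask, lc = lc,
       seq = label_sequence(mask))
})

truth_mask <- function(ph) {
  rib_mask(binary_volume(
    array(ifelse(ph$truth$rib_labels > 0L, 255L, 0L), dim(ph$truth$rib_labels)),
    ph$spec$spacing))
}

# two bright blobs on a dark noisy background, for the U-net smoke test
make_blob_pairs <- function(n, size = 32L, seed = 42L) {
  withr::with_seed(seed, replicate(n, {
    m <- matrix(0, size, size)
    yy <- matrix(seq_len(size), size, size); xx <- t(yy)
    for (b in 1:2) {
      cy <- sample(seq(8L, size - 8L), 1); cx <- sample(seq(8L, size - 8L), 1)
      r <- sample(3:6, 1)
      m[(yy - cy)^2 + (xx - cx)^2 <= r^2] <- 1
    }
    img <- m * 0.8 + 0.1 + matrix(stats::rnorm(size^2, 0, 0.05), size, size)
    list(img = pmin(pmax(img, 0), 1), mask = m)
  }, simplify = FALSE))
}

random_binary_volume <- function(d, p, spacing = c(1, 1, 1)) {
  binary_volume(array(ifelse(stats::runif(prod(d)) < p, 255L, 0L), d), spacing)
}
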