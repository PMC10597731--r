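# Fixtures built in code: small HU images for segmentation unit tests and
# compact phantom wrappers for pipeline tests.

# Nested-ellipse HU image on an arbitrary grid (no ct_slice size constraint):
# SAT ring / SM ring / VAT ring / gas core, air background.
toy_abdomen <- function(size = 180, a = 70, b = 55, sat = 10, sm = 10,
                        vat_frac = 0.5,
                        hu = c(SM = 40, VAT = -90, SAT = -105, gas = -1000,
                               air = -1000)) {
  ctr <- c(size, size) / 2 + 0.5
  ell <- function(aa, bb) {
    xs <- ((seq_len(size) - ctr[1]) / aa)^2
    ys <- ((seq_len(size) - ctr[2]) / bb)^2
    outer(xs, ys, "+") <= 1
  }
  body <- ell(a, b)
  msc <- ell(a - sat, b - sat)
  cav <- ell(a - sat - sm, b - sat - sm)
  gas <- ell((a - sat - sm) * sqrt(1 - vat_frac),
             (b - sat - sm) * sqrt(1 - vat_frac))
  img <- matrix(hu[["air"]], size, size)
  img[body & !msc] <- hu[["SAT"]]
  img[msc & !cav] <- hu[["SM"]]
  img[cav & !gas] <- hu[["VAT"]]
  img[gas] <- hu[["gas"]]
  labels <- matrix(0L, size, size)
  labels[msc & !cav] <- 1L
  labels[cav & !gas] <- 2L
  labels[body & !msc] <- 3L
  list(hu = img, labels = labels, body = body, cavity = cav)
}

# Quiet, quick phantom: few slices, optional zero noise.
quick_params <- function(seed, n_slices = 3L, noiseless = FALSE, ...) {
  extra <- list(...)
  args <- c(list(seed = seed, n_slices = n_slices), extra)
  if (noiseless && is.null(extra$hu_sd)) {
    args$hu_sd <- c(SM = 0, VAT = 0, SAT = 0, organ = 0, gas = 0)
    args$drift_sd <- 0
  }
  do.call(phantom_params, args)
}

# Independent brute-force Mann-Whitney oracle: enumerates every assignment of
# the pooled values to the two groups and counts pairs directly.
bf_mann_whitney <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a)
  n <- length(pooled)
  u_of <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  u_obs <- u_of(a, b)
  mu <- na * (n - na) / 2
  idx <- utils::combn(n, na)
  us <- apply(idx, 2, function(ii) u_of(pooled[ii], pooled[-ii]))
  list(U = u_obs, p = mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9))
}

# Per-tissue Dice of a segmentation against a ground-truth label mask.
dice_by_tissue <- function(labels, gt) {
  codes <- tissue_labels()
  vapply(c("SM", "VAT", "SAT"),
         function(t) dice(labels == codes[[t]], gt == codes[[t]]),
         numeric(1))
}
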