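# Shared fixtures: small generic continuous schemas and low-rank
# latent-factor datasets built in code.

genericSchema <- function(d) {
  markerSchema(data.frame(name = sprintf("m%02d", seq_len(d)),
                          kind = "continuous", units = "au"))
}

matrixCohort <- function(X, schema = genericSchema(nrow(X))) {
  PACohort(X, center = rep("C", ncol(X)), schema = schema)
}

# isotropic-noise low-rank data on the model's own scale (markers x patients)
lowRankData <- function(seed, d = 10, n = 300, qTrue = 3, snr = 5,
                        missRate = 0) {
  set.seed(seed)
  W <- matrix(rnorm(d * qTrue), d)
  sigma <- sqrt(sum(W^2) / d / snr)
  X <- W %*% matrix(rnorm(qTrue * n), qTrue) + rnorm(d) +
    sigma * matrix(rnorm(d * n), d)
  mask <- matrix(runif(d * n) < missRate, d, n)
  Xm <- X
  Xm[mask] <- NA
  list(full = X, masked = Xm, mask = mask, W = W, sigma = sigma)
}

principalAngles <- function(A, B) {
  qa <- qr.Q(qr(A))
  qb <- qr.Q(qr(B))
  acos(pmin(svd(crossprod(qa, qb))$d, 1))
}
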