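# Constant-velocity Kalman filter on (cx, cy, s, r) as used by SORT:
# state x = (cx, cy, s, r, vcx, vcy, vs) where s = area = w*h and
# r = aspect ratio = w/h (assumed constant). Process/measurement noise
# follows the standard SORT settings.

.kf_F <- local({
  F <- diag(7)
  F[1, 5] <- 1; F[2, 6] <- 1; F[3, 7] <- 1
  F
})
.kf_H <- cbind(diag(4), matrix(0, 4, 3))
.kf_R <- diag(c(1, 1, 10, 10))
.kf_P0 <- diag(c(10, 10, 10, 10, 1e4, 1e4, 1e4))
.kf_Q <- diag(c(1, 1, 1, 1, 0.01, 0.01, 1e-4))

box_to_z <- function(box) {
  c(box$x + box$w / 2, box$y + box$h / 2, box$w * box$h, box$w / box$h)
}

z_to_box <- function(z) {
  w <- sqrt(max(z[3], 1e-9) * max(z[4], 1e-9))
  h <- max(z[3], 1e-9) / w
  bounding_box(z[1] - w / 2, z[2] - h / 2, w, h)
}

kf_init <- function(box) {
  list(x = c(box_to_z(box), 0, 0, 0), P = .kf_P0)
}

kf_predict <- function(kf) {
  # keep the predicted area positive (SORT convention)
  if (kf$x[7] + kf$x[3] <= 0) kf$x[7] <- 0
  kf$x <- as.vector(.kf_F %*% kf$x)
  kf$P <- .kf_F %*% kf$P %*% t(.kf_F) + .kf_Q
  kf
}

kf_update <- function(kf, box) {
  z <- box_to_z(box)
  y <- z - as.vector(.kf_H %*% kf$x)
  S <- .kf_H %*% kf$P %*% t(.kf_H) + .kf_R
  K <- kf$P %*% t(.kf_H) %*% solve(S)
  kf$x <- kf$x + as.vector(K %*% y)
  kf$P <- (diag(7) - K %*% .kf_H) %*% kf$P
  kf
}

kf_box <- function(kf) z_to_box(kf$x[1:4])
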