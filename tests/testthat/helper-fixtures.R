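# small shared fixtures, all generated in code

small_design <- function(seed = 1) tnt_design(6, 4, 2, seed = seed)

full_design <- function(seed = 1) tnt_design(seed = seed)

# independent hand-rolled Benjamini-Hochberg, used as the FDR oracle
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# independent imbalance-angle oracle: force vectors in the standard
# mathematical frame (angles from +x, anticlockwise), rotated back at the
# end to the 0-degrees-at-bottom convention
angle_oracle <- function(pc, rc) {
  axis <- function(v, neg_deg, pos_deg) {
    phi <- (if (v < 0) neg_deg else pos_deg) * pi / 180
    abs(v) * c(cos(phi), sin(phi))
  }
  f <- axis(pc, -45, 135) + axis(rc, -135, 45)
  th <- atan2(f[2], f[1]) * 180 / pi + 90
  w <- ((th + 180) %% 360) - 180
  if (w == -180) 180 else w
}
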