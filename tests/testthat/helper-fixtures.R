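# Shared fixtures and independent oracles, built in code at test time.

# deterministic sequence of length n
fix_seq <- function(n) substr(strrep("ACGTTGCA", ceiling(n / 8)), 1, n)

# a bare conformation with hand-placed sites (for transform identities)
bare_conformation <- function(xyz, N = nrow(xyz)) {
  sites <- data.frame(site_id = seq_len(nrow(xyz)), strand = 1,
                      nt = seq_len(nrow(xyz)) - 1, atom = "S", base = "A",
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  structure(list(sites = sites), N = N, circular = FALSE,
            class = "conformation")
}

# independent brute-force poloidal angle: re-derived from the definition
# with its own lookups and algebra, no shared package internals
bf_poloidal <- function(frame, tracked) {
  s <- frame$sites[order(frame$sites$site_id), ]
  xyz <- frame$xyz
  N <- frame$N
  pos <- function(nt) xyz[which(s$strand == 1 & s$nt == nt & s$atom == "P"), ]
  P0 <- pos(tracked)
  Ph <- pos((tracked + round(N / 2)) %% N)
  Pq <- pos((tracked + round(N / 4)) %% N)
  P3q <- pos((tracked + round(3 * N / 4)) %% N)
  xh <- (Ph - P0) / sqrt(sum((Ph - P0)^2))
  zr <- (P3q - Pq) - sum((P3q - Pq) * xh) * xh
  zh <- zr / sqrt(sum(zr^2))
  yh <- c(zh[2] * xh[3] - zh[3] * xh[2],
          zh[3] * xh[1] - zh[1] * xh[3],
          zh[1] * xh[2] - zh[2] * xh[1])
  seg <- which(s$nt %in% ((tracked + (-5:4)) %% N))
  C <- colMeans(xyz[seg, , drop = FALSE])
  O <- C - sum((C - P0) * zh) * zh
  v <- P0 - O
  a <- atan2(sum(v * yh), sum(v * xh)) * 180 / pi
  list(phi = a, x = sum(v * xh), r = sqrt(sum(v^2)))
}

# random 3D rotation matrix (uniform axis, uniform angle)
random_rotation <- function() {
  ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
  th <- stats::runif(1, 0, 2 * pi)
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
}

# uniform-intensity disk height map
disk_image <- function(px = 41, pixel_nm = 1, centre = c(20, 20), radius = 8,
                       height = 1) {
  z <- matrix(0, px, px)
  for (r in seq_len(px)) for (cc in seq_len(px))
    if ((r - 1 - centre[1])^2 + (cc - 1 - centre[2])^2 <= radius^2)
      z[r, cc] <- height
  height_map(z, pixel_nm)
}
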