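# Shared fixtures for the test suite; everything is generated in code.

# the vessel geometry used throughout (13 cm diameter x 15 cm height)
vessel <- function() cyl_domain(radius = 65, height = 150)

# a small reconstruction problem used by several forward/recon tests
small_problem <- function(dims = c(16, 16, 20), n_src = 8, n_det = 8,
                          max_sep = 70) {
  dom <- vessel()
  grid <- build_voxel_grid(dom, dims)
  lay <- place_optodes(dom, n_src, n_det, c(2, n_src / 2), c(2, n_det / 2))
  lay <- form_channels(lay, max_sep)
  list(domain = dom, grid = grid, layout = lay)
}

table3_assumed <- function() optical_props(0.0089, 0.0062, 1.314, 1.274)

# dense double-precision reference 3D convolution (direct shifted-sum);
# offset pairing matches the package kernel: out[v] = sum_o x[v + off_o] W_o
ref_conv3d <- function(vol_list, W, b, relu = TRUE) {
  dims <- dim(vol_list[[1]])
  K <- dim(W)[3]
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  if (K == 1) off <- matrix(0, 1, 3)
  Cout <- dim(W)[2]
  out <- vector("list", Cout)
  for (co in seq_len(Cout)) {
    acc <- array(b[co], dims)
    for (o in seq_len(K)) for (ci in seq_along(vol_list)) {
      sh <- array(0, dims)
      sx <- seq_len(dims[1]) + off[o, 1]
      sy <- seq_len(dims[2]) + off[o, 2]
      sz <- seq_len(dims[3]) + off[o, 3]
      okx <- sx >= 1 & sx <= dims[1]
      oky <- sy >= 1 & sy <= dims[2]
      okz <- sz >= 1 & sz <= dims[3]
      sh[okx, oky, okz] <- vol_list[[ci]][sx[okx], sy[oky], sz[okz]]
      acc <- acc + W[ci, co, o] * sh
    }
    out[[co]] <- if (relu) pmax(acc, 0) else acc
  }
  out
}

# double-precision reference forward pass of the whole network
ref_net_forward <- function(net, x_arr) {
  P <- net$params
  depth <- net$cfg$depth
  pool <- function(vl) lapply(vl, function(a) {
    d <- dim(a)
    s <- function(i, j, k) a[seq(1 + i, d[1], 2), seq(1 + j, d[2], 2),
                             seq(1 + k, d[3], 2), drop = FALSE]
    (s(0,0,0) + s(1,0,0) + s(0,1,0) + s(1,1,0) +
       s(0,0,1) + s(1,0,1) + s(0,1,1) + s(1,1,1)) / 8
  })
  up <- function(vl) lapply(vl, function(a) {
    d <- dim(a)
    big <- array(0, d * 2)
    for (i in 0:1) for (j in 0:1) for (k in 0:1)
      big[seq(1 + i, 2 * d[1], 2), seq(1 + j, 2 * d[2], 2),
          seq(1 + k, 2 * d[3], 2)] <- a
    big
  })
  h <- list(x_arr); enc <- list()
  for (l in seq_len(depth)) {
    if (l > 1) h <- pool(h)
    convs <- if (l == depth) c("a", "b", "c", "d") else c("a", "b")
    for (ab in convs) {
      nm <- paste0("enc", l, ab)
      h <- ref_conv3d(h, P[[nm]]$W, P[[nm]]$b)
    }
    enc[[l]] <- h
  }
  d <- enc[[depth]]
  if (depth > 1) for (l in seq(depth - 1, 1)) {
    u <- up(d)
    uo <- ref_conv3d(u, P[[paste0("up", l)]]$W, P[[paste0("up", l)]]$b)
    d <- ref_conv3d(c(enc[[l]], uo), P[[paste0("dec", l)]]$W,
                    P[[paste0("dec", l)]]$b)
  }
  z <- ref_conv3d(d, P$final$W, P$final$b, relu = FALSE)
  z[[1]] + x_arr
}
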