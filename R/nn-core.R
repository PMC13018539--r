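# Minimal convolutional network machinery: same-padded conv2d (compiled),
# ReLU, 2x2 average pooling, nearest-neighbour upsampling, and Adam.
# Feature maps are H x W x C arrays; conv weights are (k*k*Cin) x Cout
# matrices in the row ordering produced by the compiled im2col.

conv_fwd <- function(x, layer) .conv2d_fwd(x, layer$w, layer$b, layer$k)

conv_bwd <- function(x, layer, dout) .conv2d_bwd(x, layer$w, dout, layer$k)

relu <- function(x) { x[x < 0] <- 0; x }

relu_bwd <- function(a, dout) { dout[a <= 0] <- 0; dout }

sigmoid <- function(x) 1 / (1 + exp(-x))

avgpool2 <- function(x) {
  h <- dim(x)[1]; w <- dim(x)[2]
  i <- seq(1L, h, 2L); j <- seq(1L, w, 2L)
  (x[i, j, , drop = FALSE] + x[i + 1L, j, , drop = FALSE] +
     x[i, j + 1L, , drop = FALSE] + x[i + 1L, j + 1L, , drop = FALSE]) / 4
}

upsample2 <- function(x) {
  x[rep(seq_len(dim(x)[1]), each = 2L),
    rep(seq_len(dim(x)[2]), each = 2L), , drop = FALSE]
}

avgpool2_bwd <- function(dout) upsample2(dout) / 4
upsample2_bwd <- function(dout) 4 * avgpool2(dout)

# He-scaled initialisation; depends on the current RNG state (callers seed it)
init_conv <- function(c_in, c_out, k) {
  fan_in <- k * k * c_in
  list(w = matrix(rnorm(fan_in * c_out, sd = sqrt(2 / fan_in)), fan_in, c_out),
       b = rep(0, c_out), k = as.integer(k))
}

# ---- parameter bookkeeping ------------------------------------------------

# Parameters live in a flat named list of conv layers (each $w, $b, $k);
# gradients mirror the structure with $dw, $db.

zero_grads <- function(params) {
  lapply(params, function(l) list(dw = 0 * l$w, db = 0 * l$b))
}

acc_grads <- function(g, g2, scale = 1) {
  for (nm in names(g)) {
    g[[nm]]$dw <- g[[nm]]$dw + scale * g2[[nm]]$dw
    g[[nm]]$db <- g[[nm]]$db + scale * g2[[nm]]$db
  }
  g
}

adam_init <- function(params) {
  list(t = 0L, m = zero_grads(params), v = zero_grads(params))
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t; c2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    for (slot in c("w", "b")) {
      g <- if (slot == "w") grads[[nm]]$dw else grads[[nm]]$db
      ms <- if (slot == "w") "dw" else "db"
      state$m[[nm]][[ms]] <- beta1 * state$m[[nm]][[ms]] + (1 - beta1) * g
      state$v[[nm]][[ms]] <- beta2 * state$v[[nm]][[ms]] + (1 - beta2) * g^2
      upd <- lr * (state$m[[nm]][[ms]] / c1) /
        (sqrt(state$v[[nm]][[ms]] / c2) + eps)
      params[[nm]][[slot]] <- params[[nm]][[slot]] - upd
    }
  }
  list(params = params, state = state)
}

# ---- U-Net ----------------------------------------------------------------

# depth = number of 2x2 poolings; input size must be divisible by 2^depth.
unet_init <- function(in_ch, out_ch, depth = 3L, width = 8L) {
  ch <- width * 2^(0:depth)  # ch[d] for level d, ch[depth+1] = bottleneck
  p <- list()
  prev <- in_ch
  for (d in seq_len(depth)) {
    p[[paste0("enc", d, "a")]] <- init_conv(prev, ch[d], 3L)
    p[[paste0("enc", d, "b")]] <- init_conv(ch[d], ch[d], 3L)
    prev <- ch[d]
  }
  p[["bota"]] <- init_conv(ch[depth], ch[depth + 1L], 3L)
  p[["botb"]] <- init_conv(ch[depth + 1L], ch[depth + 1L], 3L)
  for (d in rev(seq_len(depth))) {
    p[[paste0("dec", d, "a")]] <- init_conv(ch[d + 1L], ch[d], 3L)
    p[[paste0("dec", d, "b")]] <- init_conv(2L * ch[d], ch[d], 3L)
  }
  p[["head"]] <- init_conv(ch[1L], out_ch, 1L)
  p
}

unet_forward <- function(p, x, depth) {
  cache <- list(x0 = x)
  cur <- x
  for (d in seq_len(depth)) {
    a1 <- relu(conv_fwd(cur, p[[paste0("enc", d, "a")]]))
    a2 <- relu(conv_fwd(a1, p[[paste0("enc", d, "b")]]))
    cache[[paste0("enc", d, "in")]] <- cur
    cache[[paste0("enc", d, "a1")]] <- a1
    cache[[paste0("enc", d, "a2")]] <- a2
    cur <- avgpool2(a2)
  }
  b1 <- relu(conv_fwd(cur, p[["bota"]]))
  b2 <- relu(conv_fwd(b1, p[["botb"]]))
  cache[["botin"]] <- cur; cache[["botA"]] <- b1; cache[["botB"]] <- b2
  cur <- b2
  for (d in rev(seq_len(depth))) {
    up <- upsample2(cur)
    u1 <- relu(conv_fwd(up, p[[paste0("dec", d, "a")]]))
    cat_in <- abind3(u1, cache[[paste0("enc", d, "a2")]])
    u2 <- relu(conv_fwd(cat_in, p[[paste0("dec", d, "b")]]))
    cache[[paste0("dec", d, "up")]] <- up
    cache[[paste0("dec", d, "u1")]] <- u1
    cache[[paste0("dec", d, "cat")]] <- cat_in
    cache[[paste0("dec", d, "u2")]] <- u2
    cur <- u2
  }
  out <- conv_fwd(cur, p[["head"]])
  cache[["headin"]] <- cur
  list(out = out, cache = cache)
}

unet_backward <- function(p, cache, dout, depth) {
  g <- list()
  bw <- conv_bwd(cache[["headin"]], p[["head"]], dout)
  g[["head"]] <- list(dw = bw$dw, db = bw$db)
  dcur <- bw$dx
  dskip <- vector("list", depth)
  for (d in seq_len(depth)) {
    dcur <- relu_bwd(cache[[paste0("dec", d, "u2")]], dcur)
    bw <- conv_bwd(cache[[paste0("dec", d, "cat")]], p[[paste0("dec", d, "b")]], dcur)
    g[[paste0("dec", d, "b")]] <- list(dw = bw$dw, db = bw$db)
    nc <- dim(cache[[paste0("dec", d, "u1")]])[3]
    du1 <- bw$dx[, , seq_len(nc), drop = FALSE]
    dskip[[d]] <- bw$dx[, , nc + seq_len(dim(bw$dx)[3] - nc), drop = FALSE]
    du1 <- relu_bwd(cache[[paste0("dec", d, "u1")]], du1)
    bw <- conv_bwd(cache[[paste0("dec", d, "up")]], p[[paste0("dec", d, "a")]], du1)
    g[[paste0("dec", d, "a")]] <- list(dw = bw$dw, db = bw$db)
    dcur <- upsample2_bwd(bw$dx)
  }
  dcur <- relu_bwd(cache[["botB"]], dcur)
  bw <- conv_bwd(cache[["botA"]], p[["botb"]], dcur)
  g[["botb"]] <- list(dw = bw$dw, db = bw$db)
  db1 <- relu_bwd(cache[["botA"]], bw$dx)
  bw <- conv_bwd(cache[["botin"]], p[["bota"]], db1)
  g[["bota"]] <- list(dw = bw$dw, db = bw$db)
  dcur <- bw$dx
  for (d in rev(seq_len(depth))) {
    da2 <- avgpool2_bwd(dcur) + dskip[[d]]
    da2 <- relu_bwd(cache[[paste0("enc", d, "a2")]], da2)
    bw <- conv_bwd(cache[[paste0("enc", d, "a1")]], p[[paste0("enc", d, "b")]], da2)
    g[[paste0("enc", d, "b")]] <- list(dw = bw$dw, db = bw$db)
    da1 <- relu_bwd(cache[[paste0("enc", d, "a1")]], bw$dx)
    bw <- conv_bwd(cache[[paste0("enc", d, "in")]], p[[paste0("enc", d, "a")]], da1)
    g[[paste0("enc", d, "a")]] <- list(dw = bw$dw, db = bw$db)
    dcur <- bw$dx
  }
  g[order(match(names(g), names(p)))]
}

abind3 <- function(a, b) {
  d <- dim(a)
  out <- array(0, c(d[1], d[2], d[3] + dim(b)[3]))
  out[, , seq_len(d[3])] <- a
  out[, , d[3] + seq_len(dim(b)[3])] <- b
  out
}

# ---- plain conv encoder (classifier) --------------------------------------

# depth conv/pool stages then average pooling onto a grid x grid spatial map;
# embedding = flattened pooled features. The coarse spatial grid (rather than
# a single global average) keeps quadrant-localised signals decodable.
encoder_init <- function(in_ch, depth = 3L, width = 8L) {
  p <- list()
  prev <- in_ch
  for (d in seq_len(depth)) {
    p[[paste0("conv", d)]] <- init_conv(prev, width * 2^(d - 1L), 3L)
    prev <- width * 2^(d - 1L)
  }
  p
}

encoder_forward <- function(p, x, depth, grid = 2L) {
  cache <- list()
  cur <- x
  for (d in seq_len(depth)) {
    a <- relu(conv_fwd(cur, p[[paste0("conv", d)]]))
    cache[[paste0("in", d)]] <- cur
    cache[[paste0("a", d)]] <- a
    cur <- avgpool2(a)
  }
  # pool the final map onto a grid x grid summary
  dd <- dim(cur)
  bh <- dd[1] %/% grid; bw <- dd[2] %/% grid
  pooled <- array(0, c(grid, grid, dd[3]))
  for (gi in seq_len(grid)) for (gj in seq_len(grid)) {
    block <- cur[(gi - 1L) * bh + seq_len(bh), (gj - 1L) * bw + seq_len(bw), ,
                 drop = FALSE]
    pooled[gi, gj, ] <- apply(block, 3, mean)
  }
  cache[["final"]] <- cur
  list(emb = as.numeric(pooled), cache = cache)
}

encoder_backward <- function(p, cache, demb, depth, grid = 2L) {
  cur <- cache[["final"]]
  dd <- dim(cur)
  bh <- dd[1] %/% grid; bw <- dd[2] %/% grid
  dpool <- array(demb, c(grid, grid, dd[3]))
  dcur <- array(0, dd)
  for (gi in seq_len(grid)) for (gj in seq_len(grid)) {
    dcur[(gi - 1L) * bh + seq_len(bh), (gj - 1L) * bw + seq_len(bw), ] <-
      rep(dpool[gi, gj, ] / (bh * bw), each = bh * bw)
  }
  g <- list()
  for (d in rev(seq_len(depth))) {
    da <- avgpool2_bwd(dcur)
    da <- relu_bwd(cache[[paste0("a", d)]], da)
    bw2 <- conv_bwd(cache[[paste0("in", d)]], p[[paste0("conv", d)]], da)
    g[[paste0("conv", d)]] <- list(dw = bw2$dw, db = bw2$db)
    dcur <- bw2$dx
  }
  g[order(match(names(g), names(p)))]
}
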