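# Forward and backward passes of the residual encoder-decoder.
#
# Feature maps are (H, W, C) arrays handed to the C++ im2col/GEMM kernels;
# the topology is fixed by the spec, so the chain rule is written out
# explicitly rather than through a generic autodiff graph. All activations
# are applied after the residual addition as well as between the two
# convolutions of each block (the ResNet convention).

SELU_LAMBDA <- 1.0507009873554805
SELU_ALPHA <- 1.6732632423543772

act_fwd <- function(z, activation) {
  if (activation == "SELU") {
    neg <- z < 0
    out <- SELU_LAMBDA * z
    out[neg] <- SELU_LAMBDA * SELU_ALPHA * expm1(z[neg])
    out
  } else pmax(z, 0)
}

act_grad <- function(z, activation) {
  if (activation == "SELU") {
    g <- array(SELU_LAMBDA, dim(z))
    neg <- z < 0
    g[neg] <- SELU_LAMBDA * SELU_ALPHA * exp(z[neg])
    g
  } else (z > 0) * 1
}

sigmoid <- function(z) 1 / (1 + exp(-z))

conv_f <- function(p, nm, x, k, s)
  cs_conv2d_fwd(x, p[[paste0(nm, ".W")]], p[[paste0(nm, ".b")]], k, k, s)

conv_b <- function(p, nm, x, gout, k, s, grads) {
  r <- cs_conv2d_bwd(x, p[[paste0(nm, ".W")]], gout, k, k, s)
  grads[[paste0(nm, ".W")]] <- r$gW
  grads[[paste0(nm, ".b")]] <- as.numeric(r$gb)
  r$gx
}

# grads is an environment so the block helpers can write into it

flat_fwd <- function(p, q, x, act, res) {
  z1 <- conv_f(p, paste0(q, ".c1"), x, 3, 1)
  a1 <- act_fwd(z1, act)
  s <- conv_f(p, paste0(q, ".c2"), a1, 3, 1)
  if (res) {
    idn <- paste0(q, ".id.W")
    s <- s + if (!is.null(p[[idn]])) conv_f(p, paste0(q, ".id"), x, 1, 1) else x
  }
  list(out = act_fwd(s, act), cache = list(x = x, z1 = z1, a1 = a1, s = s))
}

flat_bwd <- function(p, q, cache, gout, act, res, grads) {
  gs <- gout * act_grad(cache$s, act)
  ga1 <- conv_b(p, paste0(q, ".c2"), cache$a1, gs, 3, 1, grads)
  gz1 <- ga1 * act_grad(cache$z1, act)
  gx <- conv_b(p, paste0(q, ".c1"), cache$x, gz1, 3, 1, grads)
  if (res) {
    idn <- paste0(q, ".id.W")
    gx <- gx + if (!is.null(p[[idn]]))
      conv_b(p, paste0(q, ".id"), cache$x, gs, 1, 1, grads) else gs
  }
  gx
}

down_fwd <- function(p, q, x, act, res) {
  z1 <- conv_f(p, paste0(q, ".c1"), x, 3, 2)
  a1 <- act_fwd(z1, act)
  s <- conv_f(p, paste0(q, ".c2"), a1, 3, 1)
  cache <- list(x = x, z1 = z1, a1 = a1)
  if (res) {
    mp <- cs_maxpool2_fwd(x)
    s <- s + conv_f(p, paste0(q, ".id"), mp$out, 1, 1)
    cache$mp <- mp
  }
  cache$s <- s
  list(out = act_fwd(s, act), cache = cache)
}

down_bwd <- function(p, q, cache, gout, act, res, grads) {
  gs <- gout * act_grad(cache$s, act)
  ga1 <- conv_b(p, paste0(q, ".c2"), cache$a1, gs, 3, 1, grads)
  gz1 <- ga1 * act_grad(cache$z1, act)
  gx <- conv_b(p, paste0(q, ".c1"), cache$x, gz1, 3, 2, grads)
  if (res) {
    gmp <- conv_b(p, paste0(q, ".id"), cache$mp$out, gs, 1, 1, grads)
    gx <- gx + cs_maxpool2_bwd(gmp, cache$mp$idx)
  }
  gx
}

up_fwd <- function(p, q, x, act, res) {
  z1 <- cs_tconv2_fwd(x, p[[paste0(q, ".t.W")]], p[[paste0(q, ".t.b")]])
  a1 <- act_fwd(z1, act)
  s <- conv_f(p, paste0(q, ".c2"), a1, 3, 1)
  cache <- list(x = x, z1 = z1, a1 = a1)
  if (res) {
    un <- cs_upnn_fwd(x, 2L)
    s <- s + conv_f(p, paste0(q, ".id"), un, 1, 1)
    cache$un <- un
  }
  cache$s <- s
  list(out = act_fwd(s, act), cache = cache)
}

up_bwd <- function(p, q, cache, gout, act, res, grads) {
  gs <- gout * act_grad(cache$s, act)
  ga1 <- conv_b(p, paste0(q, ".c2"), cache$a1, gs, 3, 1, grads)
  gz1 <- ga1 * act_grad(cache$z1, act)
  r <- cs_tconv2_bwd(cache$x, p[[paste0(q, ".t.W")]], gz1)
  grads[[paste0(q, ".t.W")]] <- r$gW
  grads[[paste0(q, ".t.b")]] <- as.numeric(r$gb)
  gx <- r$gx
  if (res) {
    gun <- conv_b(p, paste0(q, ".id"), cache$un, gs, 1, 1, grads)
    gx <- gx + cs_upnn_bwd(gun, 2L)
  }
  gx
}

head_fwd <- function(p, q, x, level) {
  z <- conv_f(p, q, x, 1, 1)
  pr <- sigmoid(z)
  out <- if (level > 0) cs_upnn_fwd(pr, 2L^level) else pr
  list(out = out[, , 1], cache = list(x = x, pr = pr, level = level))
}

head_bwd <- function(p, q, cache, gout, grads) {
  g <- array(gout, c(dim(gout), 1L))
  if (cache$level > 0) g <- cs_upnn_bwd(g, 2L^cache$level)
  gz <- g * cache$pr * (1 - cache$pr)
  conv_b(p, q, cache$x, gz, 1, 1, grads)
}

concat_ch <- function(a, b) {
  da <- dim(a)
  db <- dim(b)
  array(c(a, b), c(da[1], da[2], da[3] + db[3]))
}

#' Run the network forward on one slice
#'
#' @param network a `cs_network`.
#' @param x numeric matrix, `input_height` x `input_width` (a standardized
#'   canvas slice).
#' @param keep_cache keep all intermediate activations (needed for a
#'   subsequent backward pass).
#' @param heads compute the auxiliary supervised heads in addition to the
#'   main output (automatic when the spec enables deep supervision).
#' @return list with `outputs` — probability maps at input resolution,
#'   deepest supervised head first, the main output last (a single-element
#'   list when deep supervision is off) — and, if requested, `cache`.
#' @export
net_forward <- function(network, x, keep_cache = FALSE, heads = NULL) {
  spec <- network$spec
  p <- network$params
  if (!all(dim(x) == c(spec$input_height, spec$input_width)))
    cs_data_error(sprintf("slice is %s but the network expects %dx%d",
                          paste(dim(x), collapse = "x"),
                          spec$input_height, spec$input_width))
  if (is.null(heads)) heads <- spec$use_deep_supervision
  act <- spec$activation
  res <- spec$use_residual
  L <- spec$depth
  cache <- list()
  enc <- vector("list", L + 1L)

  h <- array(x, c(dim(x), 1L))
  fb <- flat_fwd(p, "enc0", h, act, res)
  cache$enc0 <- fb$cache
  enc[[1]] <- fb$out
  h <- fb$out
  for (l in seq_len(L)) {
    db <- down_fwd(p, sprintf("down%d", l), h, act, res)
    cache[[sprintf("down%d", l)]] <- db$cache
    fb <- flat_fwd(p, sprintf("encf%d", l), db$out, act, res)
    cache[[sprintf("encf%d", l)]] <- fb$cache
    enc[[l + 1L]] <- fb$out
    h <- fb$out
  }
  outputs <- list()
  for (l in L:1) {
    ub <- up_fwd(p, sprintf("up%d", l), h, act, res)
    cache[[sprintf("up%d", l)]] <- ub$cache
    hcat <- concat_ch(ub$out, enc[[l]])
    fb <- flat_fwd(p, sprintf("decf%d", l - 1), hcat, act, res)
    cache[[sprintf("decf%d", l - 1)]] <- fb$cache
    h <- fb$out
    if (heads && spec$use_deep_supervision) {
      hd <- head_fwd(p, sprintf("head%d", l - 1), h, l - 1L)
      cache[[sprintf("head%d", l - 1)]] <- hd$cache
      outputs[[sprintf("head%d", l - 1)]] <- hd$out
    }
  }
  hd <- head_fwd(p, "main", h, 0L)
  cache$main <- hd$cache
  outputs$main <- hd$out
  if (!keep_cache) cache <- NULL
  list(outputs = outputs, cache = cache)
}

# Backward pass: gouts is a named list of gradients w.r.t. each entry of
# `outputs`. Returns the flat named gradient list aligned with params.
net_backward <- function(network, cache, gouts) {
  spec <- network$spec
  p <- network$params
  act <- spec$activation
  res <- spec$use_residual
  L <- spec$depth
  grads <- new.env(parent = emptyenv())

  # decoder features at level l-1 (the output of decf{l-1}) receive gradient
  # from: the main head (level 0 only), the auxiliary head at that level, and
  # the next-shallower up block walked before it. Walk shallowest-first.
  gh <- head_bwd(p, "main", cache$main, gouts$main, grads)
  genc <- vector("list", L)  # gradients into encoder skips enc[[1..L]]
  for (l in 1:L) {
    nm_head <- sprintf("head%d", l - 1)
    if (!is.null(gouts[[nm_head]]) && !is.null(cache[[nm_head]]))
      gh <- gh + head_bwd(p, nm_head, cache[[nm_head]], gouts[[nm_head]], grads)
    ghcat <- flat_bwd(p, sprintf("decf%d", l - 1), cache[[sprintf("decf%d", l - 1)]],
                      gh, act, res, grads)
    cup <- cache[[sprintf("up%d", l)]]
    cu <- dim(cup$s)[3]
    gup <- ghcat[, , seq_len(cu), drop = FALSE]
    genc[[l]] <- ghcat[, , cu + seq_len(dim(ghcat)[3] - cu), drop = FALSE]
    gh <- up_bwd(p, sprintf("up%d", l), cup, gup, act, res, grads)
  }
  # gh now flows into the encoder bottleneck (output of encf{L})
  g <- gh
  for (l in L:1) {
    g <- flat_bwd(p, sprintf("encf%d", l), cache[[sprintf("encf%d", l)]],
                  g, act, res, grads)
    g <- down_bwd(p, sprintf("down%d", l), cache[[sprintf("down%d", l)]],
                  g, act, res, grads)
    g <- g + genc[[l]]
  }
  flat_bwd(p, "enc0", cache$enc0, g, act, res, grads)
  as.list(grads)
}
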