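# Finite-difference gradient checker for layers: compares analytic input and
# parameter gradients of loss = sum(forward(x) * R) against central
# differences on a random subset of coordinates.
gradcheck_layer <- function(make_layer, n = 2, h = 4, w = 4, cin = 6,
                            train = TRUE, eps = 1e-5, tol = 1e-5,
                            n_input = 25, n_param = 8) {
  layer <- make_layer()
  x <- fmap(matrix(stats::rnorm(n * h * w * cin), ncol = cin), n, h, w)
  set.seed(7)
  y <- layer$forward(x, train)
  R <- matrix(stats::rnorm(length(y)), nrow(y), ncol(y))
  refwd <- function(xx) {
    set.seed(7) # stochastic-depth draws must repeat across evaluations
    sum(unclass(layer$forward(xx, train)) * R)
  }
  analytic <- function() {
    octstitch:::zero_grads(layer)
    set.seed(7)
    y <- layer$forward(x, train)
    dy <- y
    dy[] <- R
    layer$backward(dy)
  }
  dx <- analytic()
  for (i in sample(length(x), min(n_input, length(x)))) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g <- (refwd(xp) - refwd(xm)) / (2 * eps)
    if (abs(g - unclass(dx)[i]) > tol * max(1, abs(g))) {
      return(sprintf("input grad mismatch at %d: %g vs %g", i, g,
                     unclass(dx)[i]))
    }
  }
  analytic()
  for (l in octstitch:::collect_layers(layer)) {
    for (pn in names(l$params)) {
      p <- l$params[[pn]]
      for (i in sample(length(p), min(n_param, length(p)))) {
        l$params[[pn]][i] <- p[i] + eps
        up <- refwd(x)
        l$params[[pn]][i] <- p[i] - eps
        dn <- refwd(x)
        l$params[[pn]][i] <- p[i]
        g <- (up - dn) / (2 * eps)
        if (abs(g - l$grads[[pn]][i]) > tol * max(1, abs(g))) {
          return(sprintf("param '%s' grad mismatch: %g vs %g", pn, g,
                         l$grads[[pn]][i]))
        }
      }
    }
  }
  "OK"
}
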