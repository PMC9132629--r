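# Shared fixtures and independent oracles.

# small labeled corpus with predictable token structure
tiny_corpus <- function() {
  corpus(
    text = c("I am HAPPY! happy day", "so sad, very sad!!", "fear the dark",
             "happy happy joy", "sad and blue", "dark fear rises"),
    label = c("Happy", "Sad", "Fear", "Happy", "Sad", "Fear")
  )
}

# separable two-class feature matrix: class decided by column 1 vs 2,
# rows deliberately distinct so duplicate-aware folds see unique rows
separable_fm <- function(n_per_class = 9, seed = 5) {
  set.seed(seed)
  n <- 2 * n_per_class
  V <- matrix(round(stats::runif(n * 4, 0, 0.2), 4), n, 4)
  lab <- rep(c("neg", "pos"), each = n_per_class)
  V[lab == "neg", 1] <- V[lab == "neg", 1] + 3 + seq_len(n_per_class) / 100
  V[lab == "pos", 2] <- V[lab == "pos", 2] + 3 + seq_len(n_per_class) / 100
  feature_matrix(V, lab)
}

# deterministic d = 10 landscape: features 1, 4, 7 carry the label
oracle_toy <- function() {
  set.seed(42)
  n <- 60; K <- 3
  lab <- rep(0:(K - 1), each = n / K)
  V <- matrix(round(stats::runif(n * 10), 3), n, 10)
  for (k in 0:(K - 1))
    V[lab == k, c(1, 4, 7)[k + 1]] <- V[lab == k, c(1, 4, 7)[k + 1]] + 2
  feature_matrix(V, lab, c("a", "b", "c"))
}

# Independent metrics reference: expand the confusion matrix back into
# label vectors and score each class one-vs-rest with logical masks — a
# different computational route from the matrix arithmetic under test.
ref_metrics <- function(cm) {
  K <- nrow(cm)
  yt <- integer(); yp <- integer()
  for (i in seq_len(K)) for (j in seq_len(K)) {
    yt <- c(yt, rep(i, cm[i, j])); yp <- c(yp, rep(j, cm[i, j]))
  }
  safe <- function(x) if (is.nan(x)) 0 else x
  per <- t(vapply(seq_len(K), function(c_) {
    sens <- safe(mean(yp[yt == c_] == c_))
    spec <- safe(mean(yp[yt != c_] != c_))
    prec <- safe(mean(yt[yp == c_] == c_))
    f <- if (prec + sens == 0) 0 else 2 * prec * sens / (prec + sens)
    c(sens = sens, spec = spec, prec = prec, f = f)
  }, numeric(4)))
  list(per = per, acc = mean(yt == yp),
       macro_sens = mean(per[, "sens"]), macro_spec = mean(per[, "spec"]),
       macro_f = mean(per[, "f"]))
}

# central finite-difference gradient of the 0.5*sum((o - t)^2) loss
fd_gradients <- function(model, x, target, h = 1e-5) {
  loss <- function(m) {
    o <- bpnn_forward(m, x)$output
    0.5 * sum((drop(o) - target)^2)
  }
  grad_of <- function(field) {
    g <- model[[field]]
    for (i in seq_along(g)) {
      mp <- model; mp[[field]][i] <- mp[[field]][i] + h
      mm <- model; mm[[field]][i] <- mm[[field]][i] - h
      g[i] <- (loss(mp) - loss(mm)) / (2 * h)
    }
    g
  }
  list(W_in_hidden = grad_of("W_in_hidden"),
       b_hidden = grad_of("b_hidden"),
       W_hidden_out = grad_of("W_hidden_out"),
       b_out = grad_of("b_out"))
}

# max deviation between analytic and finite-difference gradients,
# relative with an absolute floor of 1 (gradients here are O(1e-3..1e-1))
gradient_gap <- function(model, x, target) {
  an <- bpnn_backward(model, x, target)
  fd <- fd_gradients(model, x, target)
  max(vapply(names(an), function(f)
    max(abs(an[[f]] - fd[[f]]) / pmax(1, abs(fd[[f]]))), numeric(1)))
}
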