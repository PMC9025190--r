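# Independent oracles shared across test files.

# Minimise the elastic-net objective directly with L-BFGS-B on the
# positive/negative split (beta = bp - bn, bp, bn >= 0), which turns the
# penalised problem into a smooth box-constrained one.
enet_oracle <- function(y, X, lambda, alpha) {
  n <- length(y); p <- ncol(X)
  fn <- function(par) {
    b0 <- par[1]; bp <- par[2:(p + 1)]; bn <- par[(p + 2):(2 * p + 1)]
    b <- bp - bn
    sum((y - b0 - X %*% b)^2) / (2 * n) +
      lambda * sum((1 - alpha) / 2 * b^2 + alpha * (bp + bn))
  }
  best <- NULL
  for (init in list(rep(0, 2 * p + 1), c(mean(y), rep(0.1, 2 * p)))) {
    o <- optim(init, fn, method = "L-BFGS-B",
               lower = c(-Inf, rep(0, 2 * p)),
               control = list(maxit = 2000, factr = 10))
    if (is.null(best) || o$value < best$value) best <- o
  }
  list(beta0 = best$par[1],
       beta = best$par[2:(p + 1)] - best$par[(p + 2):(2 * p + 1)],
       value = best$value)
}

# Assemble a recon_db from a 0/1 strain x reaction carriage matrix.
make_db <- function(carriage, roles = NULL, phyla = NULL) {
  strains <- data.frame(strain_id = rownames(carriage),
                        phylum = phyla %||% rep("Firmicutes", nrow(carriage)),
                        stringsAsFactors = FALSE)
  reactions <- data.frame(reaction_id = colnames(carriage),
                          metabolite = "benzoate",
                          role = roles %||% rep_len(c("produce", "degrade",
                                                      "transport"),
                                                    ncol(carriage)),
                          stringsAsFactors = FALSE)
  idx <- which(carriage == 1, arr.ind = TRUE)
  recon_db(strains, reactions,
           data.frame(strain_id = rownames(carriage)[idx[, 1]],
                      reaction_id = colnames(carriage)[idx[, 2]],
                      stringsAsFactors = FALSE),
           data.frame(strain_id = character(), metabolite = character(),
                      stringsAsFactors = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
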