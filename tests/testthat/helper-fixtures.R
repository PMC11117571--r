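# shared fixtures and independent oracles

randNonneg <- function(m, n, seed = 1) {
  set.seed(seed)
  matrix(runif(m * n, 0.01, 1), m, n)
}

# reference recursion for the activation filter: plain R loop
loopNeuralActivation <- function(e, params, fs) {
  d <- as.integer(round(params$dMs * fs / 1000))
  u <- numeric(length(e))
  for (t in seq_along(e)) {
    ed <- if (t - d >= 1) e[t - d] else 0
    u1 <- if (t >= 2) u[t - 1] else 0
    u2 <- if (t >= 3) u[t - 2] else 0
    u[t] <- params$alpha * ed - params$beta1 * u1 - params$beta2 * u2
  }
  u
}

# best cosine matching of recovered synergy columns to truth over all
# column permutations (k <= 5 keeps this exact and cheap)
bestPermCosine <- function(West, Wtrue) {
  k <- ncol(Wtrue)
  cs <- abs(crossprod(West / sqrt(colSums(West^2) + 1e-300),
                      Wtrue / sqrt(colSums(Wtrue^2) + 1e-300)))
  perms <- .allPerms(k)
  best <- -Inf
  for (p in perms) best <- max(best, mean(cs[cbind(p, seq_len(k))]))
  best
}

.allPerms <- function(k) {
  if (k == 1) return(list(1L))
  out <- list()
  for (p in .allPerms(k - 1L)) for (pos in 0:(k - 1L))
    out[[length(out) + 1L]] <- append(p, k, after = pos)
  out
}

# cross-implementation NMF oracle: scikit-learn multiplicative updates from
# an identical initialization; returns the final squared-Frobenius loss
sklearnNMFLoss <- function(V, W0, C0, maxIter) {
  td <- tempfile("nmf")
  dir.create(td)
  on.exit(unlink(td, recursive = TRUE), add = TRUE)
  write.table(V, file.path(td, "V.csv"), sep = ",",
              row.names = FALSE, col.names = FALSE)
  write.table(W0, file.path(td, "W.csv"), sep = ",",
              row.names = FALSE, col.names = FALSE)
  write.table(C0, file.path(td, "H.csv"), sep = ",",
              row.names = FALSE, col.names = FALSE)
  py <- sprintf("
import numpy as np
from sklearn.decomposition import NMF
import warnings
warnings.filterwarnings('ignore')
V = np.loadtxt('%s/V.csv', delimiter=',')
W0 = np.loadtxt('%s/W.csv', delimiter=',')
H0 = np.loadtxt('%s/H.csv', delimiter=',')
if W0.ndim == 1: W0 = W0[:, None]
if H0.ndim == 1: H0 = H0[None, :]
m = NMF(n_components=W0.shape[1], init='custom', solver='mu',
        beta_loss='frobenius', tol=0.0, max_iter=%d)
W = m.fit_transform(V, W=W0, H=H0)
H = m.components_
print(repr(float(np.sum((V - W @ H) ** 2))))
", td, td, td, maxIter)
  out <- system2("python", c("-c", shQuote(py)), stdout = TRUE, stderr = FALSE)
  as.numeric(out[length(out)])
}

# tiny synthetic pools of jittered archetype vectors for sorting tests
archetypePool <- function(archetypes, perArch, sd = 0.05, seed = 1) {
  set.seed(seed)
  D <- do.call(cbind, lapply(seq_len(perArch), function(i) {
    A <- pmax(archetypes + matrix(rnorm(length(archetypes), 0, sd),
                                  nrow(archetypes)), 0)
    sweep(A, 2, sqrt(colSums(A^2)), "/")
  }))
  D
}
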