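# Independent brute-force oracles, deliberately loop-based and separate from
# the package's matrix-algebra implementations.

# mean pairwise (weighted) agreement kappa over a complete items x raters
# matrix; categories in ordinal order
oracle_fleiss <- function(mat, categories, weighted = FALSE) {
  K <- length(categories)
  wfun <- function(a, b) {
    if (!weighted) return(as.numeric(a == b))
    1 - abs(match(a, categories) - match(b, categories)) / (K - 1)
  }
  N <- nrow(mat); n <- ncol(mat)
  po_items <- numeric(N)
  for (i in seq_len(N)) {
    s <- 0
    for (a in seq_len(n)) for (b in seq_len(n)) {
      if (a != b) s <- s + wfun(mat[i, a], mat[i, b])
    }
    po_items[i] <- s / (n * (n - 1))
  }
  p <- vapply(categories, function(cc) mean(mat == cc), 0)
  pe <- 0
  for (j in seq_len(K)) for (k in seq_len(K)) {
    pe <- pe + p[j] * p[k] * wfun(categories[j], categories[k])
  }
  unname((mean(po_items) - pe) / (1 - pe))
}

oracle_cohen <- function(r1, r2, categories, weighted = FALSE) {
  K <- length(categories)
  wfun <- function(a, b) {
    if (!weighted) return(as.numeric(a == b))
    1 - abs(match(a, categories) - match(b, categories)) / (K - 1)
  }
  n <- length(r1)
  po <- mean(mapply(wfun, r1, r2))
  pe <- 0
  for (j in seq_len(K)) for (k in seq_len(K)) {
    pe <- pe + mean(r1 == categories[j]) * mean(r2 == categories[k]) *
      wfun(categories[j], categories[k])
  }
  unname((po - pe) / (1 - pe))
}

# alpha straight from its definition: observed vs expected mean pairwise
# squared difference, pair enumeration item by item
oracle_alpha <- function(mat, categories, metric = "ordinal") {
  vals_by_item <- apply(mat, 1, function(r) r[!is.na(r)], simplify = FALSE)
  vals_by_item <- vals_by_item[lengths(vals_by_item) >= 2]
  pooled <- unlist(vals_by_item)
  nc <- vapply(categories, function(cc) sum(pooled == cc), 0)
  n <- sum(nc)
  d2 <- function(a, b) {
    ia <- match(a, categories); ib <- match(b, categories)
    if (metric == "nominal") return(as.numeric(ia != ib))
    lo <- min(ia, ib); hi <- max(ia, ib)
    (sum(nc[lo:hi]) - (nc[lo] + nc[hi]) / 2)^2
  }
  Do <- 0
  for (vals in vals_by_item) {
    m <- length(vals)
    for (a in seq_len(m)) for (b in seq_len(m)) {
      if (a != b) Do <- Do + d2(vals[a], vals[b]) / (m - 1)
    }
  }
  Do <- Do / n
  De <- 0
  for (j in seq_along(categories)) for (k in seq_along(categories)) {
    if (j != k) De <- De + nc[j] * nc[k] * d2(categories[j], categories[k])
  }
  De <- De / (n * (n - 1))
  unname(1 - Do / De)
}

# type-7 quantile from the interpolation formula, written out
oracle_quantile7 <- function(x, p) {
  x <- sort(x)
  h <- (length(x) - 1) * p + 1
  lo <- floor(h)
  if (lo == length(x)) return(x[lo])
  x[lo] + (h - lo) * (x[lo + 1] - x[lo])
}

# brute-force MLA: fine-grid argmax of P(group | age)
oracle_mla <- function(model, group_index, age_min, age_max, step = 0.001) {
  grid <- seq(age_min, age_max, by = step)
  t <- if (model$transform == "log") log(grid) else grid
  taue <- c(-Inf, unname(model$cutpoints), Inf)
  p <- pnorm(taue[group_index + 1] - model$slope * t) -
    pnorm(taue[group_index] - model$slope * t)
  grid[which.max(p)]
}

# default cohort conditions shared across tests
true_group_ages <- function() c(15.7, 17.1, 19.5, 21.0, 22.4)
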