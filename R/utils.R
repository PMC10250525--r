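# Evaluate `code` under a temporary RNG state seeded with `seed`.
# seed = NULL leaves the ambient RNG untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# All permutations of 1..k in lexicographic order (k! rows).
permutations <- function(k) {
  stopifnot(k >= 1)
  if (k == 1) return(matrix(1L, 1L, 1L))
  sub <- permutations(k - 1L)
  out <- vector("list", k)
  elems <- seq_len(k)
  for (i in elems) {
    rest <- elems[-i]
    out[[i]] <- cbind(i, matrix(rest[sub], nrow(sub), k - 1L))
  }
  res <- do.call(rbind, out)
  dimnames(res) <- NULL
  storage.mode(res) <- "integer"
  res
}

# Numeric matrix of the data columns used for fitting: all numeric columns
# except a true-label column named "component".
data_matrix <- function(data) {
  if (is.matrix(data)) {
    storage.mode(data) <- "double"
    return(data)
  }
  stopifnot(is.data.frame(data))
  keep <- vapply(data, is.numeric, logical(1)) & names(data) != "component"
  if (!any(keep)) stop("`data` has no numeric variable columns", call. = FALSE)
  as.matrix(data[keep])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
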