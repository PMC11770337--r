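# Shared test helpers: small explicit tables and independent oracles.

# Energy tables from an explicit one-body matrix and a function
# f(i, a, j, b) giving the i<j two-body entries.
tables_from <- function(ob, f = function(i, a, j, b) 0,
                        alphabet = default_alphabet()[seq_len(ncol(ob))]) {
  n <- nrow(ob)
  A <- length(alphabet)
  tb <- array(0, dim = c(A, n, A, n))
  for (i in seq_len(n)) for (j in seq_len(n)) if (i < j)
    for (a in seq_len(A)) for (b in seq_len(A))
      tb[a, i, b, j] <- f(i, a, j, b)
  energy_tables(ob, tb, alphabet, conformation_id = "test")
}

# Independent Potts score: plain double loop over the assignment matrix,
# written differently from the package implementation.
naive_score <- function(model, seq) {
  al <- model$tables$alphabet
  a <- assignment_from_sequence(seq, al)
  s <- model$penalty
  for (i in seq_len(nrow(a))) for (x in seq_along(al))
    if (a[i, x] == 1) s <- s + model$tables$one_body[i, x]
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(a))) if (i < j)
    for (x in seq_along(al)) for (y in seq_along(al))
      if (a[i, x] == 1 && a[j, y] == 1)
        s <- s + model$lambda * model$tables$two_body[x, i, y, j]
  unname(s)
}

# Independent exhaustive minimizer based on expand.grid (different
# enumeration order and scoring path from solve_exhaustive).
naive_exhaustive <- function(model) {
  al <- model$tables$alphabet
  n <- model$tables$n
  grid <- do.call(expand.grid, c(rep(list(al), n), stringsAsFactors = FALSE))
  sc <- apply(grid, 1L, function(s) potts_score(model, unname(s)))
  keys <- apply(grid, 1L, paste, collapse = "")
  ord <- order(sc, keys)
  list(sequence = unname(unlist(grid[ord[1L], ])), score = sc[ord[1L]])
}

# Small cached toy conformation for geometry/energy tests.
toy_conf_cache <- new.env()
get_toy_conf <- function(n = 4, seed = 11) {
  key <- paste(n, seed)
  if (is.null(toy_conf_cache[[key]]))
    toy_conf_cache[[key]] <- make_toy_system(n, seed = seed, slab_margin = 4)
  toy_conf_cache[[key]]
}
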