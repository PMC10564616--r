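# Independent brute-force oracles, deliberately written without igraph:
# components by union-find, articulation points and bridges by
# remove-and-recount.

uf_count <- function(n, a, b) {
  if (n == 0L) return(0L)
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (i in seq_along(a)) {
    ra <- find(a[i])
    rb <- find(b[i])
    if (ra != rb) parent[ra] <- rb
  }
  length(unique(vapply(seq_len(n), find, integer(1))))
}

graph_index <- function(nodes, edges) {
  idx <- seq_along(nodes)
  names(idx) <- nodes
  list(n = length(nodes),
       a = unname(idx[edges$from]),
       b = unname(idx[edges$to]))
}

oracle_components <- function(nodes, edges) {
  gi <- graph_index(nodes, edges)
  uf_count(gi$n, gi$a, gi$b)
}

# v is an articulation point iff removing it increases the component count
# among the remaining vertices: comp(G - v) = uf_count without v's edges - 1
oracle_articulation <- function(nodes, edges) {
  gi <- graph_index(nodes, edges)
  c0 <- uf_count(gi$n, gi$a, gi$b)
  hit <- vapply(seq_len(gi$n), function(v) {
    keep <- gi$a != v & gi$b != v
    (uf_count(gi$n, gi$a[keep], gi$b[keep]) - 1L) > c0
  }, logical(1))
  sort(nodes[hit])
}

oracle_bridges <- function(nodes, edges) {
  gi <- graph_index(nodes, edges)
  c0 <- uf_count(gi$n, gi$a, gi$b)
  m <- length(gi$a)
  if (m == 0L) {
    return(data.frame(from = character(0), to = character(0),
                      stringsAsFactors = FALSE))
  }
  hit <- vapply(seq_len(m), function(e) {
    uf_count(gi$n, gi$a[-e], gi$b[-e]) > c0
  }, logical(1))
  lo <- pmin(edges$from[hit], edges$to[hit])
  hi <- pmax(edges$from[hit], edges$to[hit])
  o <- order(lo, hi, method = "radix")
  data.frame(from = lo[o], to = hi[o], stringsAsFactors = FALSE)
}

# simple random graph as an interactome: n nodes, ~m distinct edges, a share
# of nodes marked as small molecules
random_net <- function(n, m, sm_share = 0.3) {
  nodes <- sprintf("N%03d", seq_len(n))
  cls <- ifelse(stats::runif(n) < sm_share, "SMALL_MOLECULE", "ACCESSIONED")
  if (m > 0L && n >= 2L) {
    a <- sample.int(n, m, replace = TRUE)
    b <- sample.int(n, m, replace = TRUE)
    keep <- a != b
    lo <- pmin(a[keep], b[keep])
    hi <- pmax(a[keep], b[keep])
    u <- !duplicated(paste(lo, hi))
    edges <- data.frame(from = nodes[lo[u]], to = nodes[hi[u]],
                        stringsAsFactors = FALSE)
  } else {
    edges <- NULL
  }
  interaction_network(data.frame(key = nodes, class = cls,
                                 stringsAsFactors = FALSE), edges)
}
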