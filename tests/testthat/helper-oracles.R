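# Shared fixtures and independent oracles.

options(finstab.verbose = FALSE)

# random lognormal species x month panel
rand_panel <- function(n, T = 5L) {
  x <- matrix(exp(rnorm(n * T)), n, T)
  colnames(x) <- seq_len(T)
  x
}

# brute-force oracle: variance of the column-sum series equals the sum of
# all entries of the sample covariance matrix of the species rows
cov_sum_oracle <- function(x) sum(cov(t(x)))

# ---- graphical d-separation oracle -----------------------------------------
# Moralized-ancestral-graph test: u and v are d-separated given cond iff
# they are disconnected in the moral graph of the subgraph induced by the
# ancestral closure of {u, v} + cond, after deleting cond.

oracle_ancestors <- function(edges, nodes) {
  # returns list node -> ancestors (not including itself)
  anc <- setNames(vector("list", length(nodes)), nodes)
  changed <- TRUE
  for (n in nodes) anc[[n]] <- character(0)
  while (changed) {
    changed <- FALSE
    for (i in seq_len(nrow(edges))) {
      a <- edges$cause[i]; b <- edges$effect[i]
      new <- union(anc[[b]], union(a, anc[[a]]))
      if (length(new) > length(anc[[b]])) {
        anc[[b]] <- new
        changed <- TRUE
      }
    }
  }
  anc
}

oracle_dsep <- function(edges, u, v, cond = character(0)) {
  nodes <- unique(c(edges$cause, edges$effect, u, v, cond))
  anc <- oracle_ancestors(edges, nodes)
  keep <- unique(c(u, v, cond,
                   unlist(anc[c(u, v, cond)], use.names = FALSE)))
  sub <- edges[edges$cause %in% keep & edges$effect %in% keep, , drop = FALSE]
  # moralize: undirected skeleton + marry parents of each node
  und <- rbind(sub[c("cause", "effect")],
               do.call(rbind, lapply(keep, function(w) {
                 pa <- sub$cause[sub$effect == w]
                 if (length(pa) < 2L) return(NULL)
                 cmb <- t(combn(pa, 2L))
                 data.frame(cause = cmb[, 1L], effect = cmb[, 2L],
                            stringsAsFactors = FALSE)
               })))
  # delete conditioning nodes, then BFS from u
  keep2 <- setdiff(keep, cond)
  und <- und[und$cause %in% keep2 & und$effect %in% keep2, , drop = FALSE]
  frontier <- u; seen <- u
  while (length(frontier)) {
    nxt <- unique(c(und$effect[und$cause %in% frontier],
                    und$cause[und$effect %in% frontier]))
    nxt <- setdiff(nxt, seen)
    if (v %in% nxt) return(FALSE)   # connected -> not d-separated
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  TRUE
}

# enumerate all labelled DAGs on `n` nodes (as edge data frames); the empty
# graph is skipped because a path model needs at least one edge
enumerate_dags <- function(n) {
  nodes <- letters[seq_len(n)]
  pairs <- t(combn(nodes, 2L))
  m <- nrow(pairs)
  out <- list()
  # each unordered pair: absent (0), forward (1), backward (2)
  for (code in seq_len(3^m - 1L)) {
    digits <- (code %/% 3^(seq_len(m) - 1L)) %% 3
    if (all(digits == 0)) next
    e <- data.frame(cause = character(0), effect = character(0),
                    stringsAsFactors = FALSE)
    for (k in seq_len(m)) {
      if (digits[k] == 1) e <- rbind(e, data.frame(cause = pairs[k, 1L],
                                                   effect = pairs[k, 2L]))
      if (digits[k] == 2) e <- rbind(e, data.frame(cause = pairs[k, 2L],
                                                   effect = pairs[k, 1L]))
    }
    if (is_acyclic(e)) out[[length(out) + 1L]] <- e
  }
  out
}

is_acyclic <- function(edges) {
  nodes <- unique(c(edges$cause, edges$effect))
  e <- edges
  repeat {
    if (!nrow(e)) return(TRUE)
    sinks <- setdiff(nodes, e$cause)
    if (!length(sinks)) return(FALSE)
    nodes <- setdiff(nodes, sinks)
    e <- e[!e$effect %in% sinks, , drop = FALSE]
  }
}

random_dag <- function(n_nodes = 5L, p_edge = 0.4) {
  nodes <- letters[seq_len(n_nodes)]
  ord <- sample(nodes)            # random topological order
  e <- data.frame(cause = character(0), effect = character(0),
                  stringsAsFactors = FALSE)
  for (i in seq_len(n_nodes - 1L)) {
    for (j in (i + 1L):n_nodes) {
      if (runif(1) < p_edge) {
        e <- rbind(e, data.frame(cause = ord[i], effect = ord[j],
                                 stringsAsFactors = FALSE))
      }
    }
  }
  e
}

# tiny long-record fixture used by dataio tests
make_records <- function() {
  grid <- expand.grid(month = c(3L, 5L, 7L, 9L, 11L),
                      species = c("alewife", "bluefish"),
                      stringsAsFactors = FALSE)
  data.frame(region = "MD", year = 2010L, month = grid$month,
             species = grid$species, quantity_kind = "harvest_kg",
             value = seq_len(nrow(grid)) * 10,
             stringsAsFactors = FALSE)
}
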