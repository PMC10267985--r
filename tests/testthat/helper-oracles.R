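# Independent oracles, deliberately naive: no igraph, no survival, no phyper.

# Random connected undirected simple graph as an adjacency matrix.
random_connected_adj <- function(n, p = 0.45) {
    repeat {
        a <- matrix(0L, n, n)
        up <- upper.tri(a)
        a[up] <- as.integer(runif(sum(up)) < p)
        a <- a + t(a)
        if (oracle_connected(a)) return(a)
    }
}

oracle_connected <- function(a) {
    n <- nrow(a)
    seen <- c(1L); frontier <- c(1L)
    while (length(frontier)) {
        nb <- unique(unlist(lapply(frontier, function(v) which(a[v, ] > 0))))
        frontier <- setdiff(nb, seen)
        seen <- union(seen, frontier)
    }
    length(seen) == n
}

# Exhaustive enumeration of all simple paths between every ordered pair by
# depth-first search; shortest ones define distances, path counts and
# through-node counts. Only feasible for tiny graphs (n <= 8).
oracle_all_shortest_paths <- function(a) {
    n <- nrow(a)
    paths <- list()
    dfs <- function(v, target, visited, path) {
        if (v == target) {
            paths[[length(paths) + 1L]] <<- path
            return(invisible())
        }
        for (w in which(a[v, ] > 0)) {
            if (!w %in% visited) dfs(w, target, c(visited, w), c(path, w))
        }
    }
    out <- vector("list", n * n)
    for (s in seq_len(n)) for (t in seq_len(n)) {
        if (s >= t) next
        paths <- list()
        dfs(s, t, s, s)
        lens <- vapply(paths, length, 1L)
        keep <- paths[lens == min(lens)]
        out[[(s - 1L) * n + t]] <- keep
    }
    out
}

# Degree, normalized betweenness and closeness via the path enumeration.
oracle_centralities <- function(a) {
    n <- nrow(a)
    sp <- oracle_all_shortest_paths(a)
    dist <- matrix(0, n, n)
    bc_raw <- numeric(n)
    for (s in seq_len(n)) for (t in seq_len(n)) {
        if (s >= t) next
        ps <- sp[[(s - 1L) * n + t]]
        d <- length(ps[[1]]) - 1L
        dist[s, t] <- dist[t, s] <- d
        sigma <- length(ps)
        for (v in seq_len(n)) {
            if (v == s || v == t) next
            through <- sum(vapply(ps, function(p) v %in% p, TRUE))
            bc_raw[v] <- bc_raw[v] + through / sigma
        }
    }
    denom <- (n - 1) * (n - 2) / 2
    list(dc = rowSums(a),
         bc = if (denom > 0) bc_raw / denom else rep(0, n),
         cc = (n - 1) / rowSums(dist))
}

# Upper-tail hypergeometric P(X >= k) by enumerating every n-subset of a
# universe of N elements whose first K elements form the annotated set.
oracle_hyper_upper <- function(N, K, n, k) {
    draws <- utils::combn(N, n)
    mean(colSums(draws <= K) >= k)
}

# Two-group log-rank chi-square by direct O - E accumulation over the
# distinct event times.
oracle_logrank_chisq <- function(time, event, arm) {
    arm <- as.character(arm)
    g1 <- unique(arm)[1]
    o_minus_e <- 0; v <- 0
    for (t in sort(unique(time[event == 1]))) {
        at_risk <- time >= t
        n_tot <- sum(at_risk)
        n1 <- sum(at_risk & arm == g1)
        d <- sum(event == 1 & time == t)
        d1 <- sum(event == 1 & time == t & arm == g1)
        o_minus_e <- o_minus_e + (d1 - d * n1 / n_tot)
        if (n_tot > 1)
            v <- v + d * (n1 / n_tot) * (1 - n1 / n_tot) *
                (n_tot - d) / (n_tot - 1)
    }
    o_minus_e^2 / v
}

# Kaplan-Meier survival values at the event times, product-limit by hand.
oracle_km <- function(time, event) {
    ts <- sort(unique(time[event == 1]))
    s <- 1
    surv <- numeric(length(ts))
    for (i in seq_along(ts)) {
        n_risk <- sum(time >= ts[i])
        d <- sum(time == ts[i] & event == 1)
        s <- s * (1 - d / n_risk)
        surv[i] <- s
    }
    list(time = ts, surv = surv)
}

# Tiny deterministic interactome for hand-checkable examples.
path_graph <- function(labels) {
    Interactome(cbind(labels[-length(labels)], labels[-1]))
}
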