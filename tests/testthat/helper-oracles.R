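# Independent oracles used against the package's implementations.

# iterative flood-fill connected-component count (and labels)
oracle_flood_label <- function(mask, connectivity = 8L) {
    nr <- nrow(mask); nc <- ncol(mask)
    lab <- matrix(0L, nr, nc)
    if (connectivity == 8L) {
        di <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
        dj <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
    } else {
        di <- c(-1L, 0L, 0L, 1L)
        dj <- c(0L, -1L, 1L, 0L)
    }
    k <- 0L
    for (j0 in seq_len(nc)) for (i0 in seq_len(nr)) {
        if (!mask[i0, j0] || lab[i0, j0]) next
        k <- k + 1L
        stack <- list(c(i0, j0))
        lab[i0, j0] <- k
        while (length(stack)) {
            p <- stack[[length(stack)]]
            stack[[length(stack)]] <- NULL
            for (d in seq_along(di)) {
                i <- p[1] + di[d]; j <- p[2] + dj[d]
                if (i >= 1 && i <= nr && j >= 1 && j <= nc &&
                    mask[i, j] && !lab[i, j]) {
                    lab[i, j] <- k
                    stack[[length(stack) + 1L]] <- c(i, j)
                }
            }
        }
    }
    list(labels = lab, n = k)
}

oracle_flood_betti <- function(mask) {
    b0 <- oracle_flood_label(mask, 8L)$n
    bg <- oracle_flood_label(!mask, 4L)
    if (bg$n == 0L) return(c(b0 = b0, b1 = 0L))
    border <- unique(c(bg$labels[1, ], bg$labels[nrow(mask), ],
                       bg$labels[, 1], bg$labels[, ncol(mask)]))
    border <- border[border > 0L]
    c(b0 = b0, b1 = bg$n - length(unique(border)))
}

# Euler characteristic for (8-connected foreground, 4-connected holes) by
# local 2x2 pattern counting (bit quads): chi = (Q1 - Q3 - 2 QD) / 4
oracle_euler8 <- function(mask) {
    m <- matrix(0L, nrow(mask) + 2L, ncol(mask) + 2L)
    m[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- mask * 1L
    nr <- nrow(m); nc <- ncol(m)
    a <- m[-nr, -nc]; b <- m[-nr, -1]; c_ <- m[-1, -nc]; d <- m[-1, -1]
    s <- a + b + c_ + d
    q1 <- sum(s == 1L)
    q3 <- sum(s == 3L)
    qd <- sum(s == 2L & ((a == 1L & d == 1L) | (b == 1L & c_ == 1L)))
    (q1 - q3 - 2L * qd) / 4L
}

# brute-force moment-mismatch threshold: for every split {g <= t | g > t}
# solve the two representative levels matching the first two moments and
# score the third-moment error of the induced two-level image
oracle_moments_brute <- function(counts) {
    p <- counts / sum(counts)
    g <- 0:255
    m1 <- sum(p * g); m2 <- sum(p * g^2); m3 <- sum(p * g^3)
    cd <- m2 - m1^2
    if (cd < 1e-9) return(as.integer(round(m1)))
    cum <- cumsum(p)
    best_t <- NA_integer_; best_err <- Inf
    for (t in 0:255) {
        q0 <- cum[t + 1L]; q1 <- 1 - q0
        if (q0 <= 0 || q1 <= 0) next
        z0 <- m1 - sqrt(cd * q1 / q0)
        z1 <- m1 + sqrt(cd * q0 / q1)
        err <- abs(q0 * z0^3 + q1 * z1^3 - m3)
        if (err < best_err - 1e-9) {
            best_err <- err
            best_t <- t
        }
    }
    best_t
}

random_histogram <- function() {
    counts <- integer(256)
    n <- sample(c(2L, 3L, 10L, 50L, 256L), 1L)
    lv <- sample(0:255, n)
    counts[lv + 1L] <- stats::rpois(n, sample(c(2, 20, 200), 1L)) + 1L
    build_histogram(matrix(rep(0:255, counts), ncol = 1L,
                           nrow = sum(counts)))
}
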