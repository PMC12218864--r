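# Independent oracles used by the tests. These deliberately re-derive
# results through different algorithms than the package (path enumeration
# instead of moralization, sidereal-time solar altitude scan instead of the
# equation-of-time closed form, explicit marginalization instead of the
# factorized likelihood) so that agreement is evidence, not tautology.

## ---- d-separation by brute-force path enumeration ----

# edges: data.frame(from, to). Enumerate all simple undirected paths x..y,
# then apply the collider/non-collider blocking rules triple by triple.
oracle_all_paths <- function(edges, x, y, nodes) {
  adj <- lapply(setNames(nodes, nodes), function(n) {
    unique(c(edges$to[edges$from == n], edges$from[edges$to == n]))
  })
  paths <- list()
  walk <- function(path) {
    last <- path[length(path)]
    if (last == y) {
      paths[[length(paths) + 1]] <<- path
      return()
    }
    for (nb in adj[[last]]) if (!nb %in% path) walk(c(path, nb))
  }
  walk(x)
  paths
}

oracle_descendants <- function(edges, node) {
  out <- character()
  frontier <- node
  while (length(frontier)) {
    nxt <- setdiff(unique(edges$to[edges$from %in% frontier]), out)
    out <- c(out, nxt)
    frontier <- nxt
  }
  setdiff(out, node)
}

oracle_path_blocked <- function(edges, path, z) {
  if (length(path) < 3) {
    return(FALSE)
  }
  has_edge <- function(a, b) any(edges$from == a & edges$to == b)
  for (i in 2:(length(path) - 1)) {
    a <- path[i - 1]
    b <- path[i]
    c <- path[i + 1]
    collider <- has_edge(a, b) && has_edge(c, b)
    if (collider) {
      if (!(b %in% z) && !length(intersect(oracle_descendants(edges, b), z))) {
        return(TRUE)
      }
    } else {
      if (b %in% z) {
        return(TRUE)
      }
    }
  }
  FALSE
}

oracle_d_separated <- function(edges, x, y, z, nodes) {
  paths <- oracle_all_paths(edges, x, y, nodes)
  all(vapply(paths, oracle_path_blocked, TRUE, edges = edges, z = z))
}

# back-door check: clause (i) by descendant enumeration, clause (ii) by
# testing only the paths whose first step enters the exposure
oracle_backdoor <- function(edges, exposure, outcome, z, nodes) {
  if (length(intersect(z, oracle_descendants(edges, exposure)))) {
    return(FALSE)
  }
  paths <- oracle_all_paths(edges, exposure, outcome, nodes)
  into_x <- vapply(paths, function(p) {
    any(edges$from == p[2] & edges$to == p[1])
  }, TRUE)
  all(vapply(paths[into_x], oracle_path_blocked, TRUE, edges = edges, z = z))
}

random_dag <- function(n_nodes, p_edge = 0.35) {
  nodes <- LETTERS[seq_len(n_nodes)]
  from <- character()
  to <- character()
  for (i in seq_len(n_nodes - 1)) {
    for (j in (i + 1):n_nodes) {
      if (runif(1) < p_edge) {
        from <- c(from, nodes[i])
        to <- c(to, nodes[j])
      }
    }
  }
  if (!length(from)) {
    from <- nodes[1]
    to <- nodes[2]
  }
  data.frame(from = from, to = to, stringsAsFactors = FALSE)
}

## ---- solar altitude by an independent formulation ----

# Approximate solar RA/declination (Astronomical Almanac low-precision
# series) + Greenwich sidereal time -> altitude; dawn/dusk located by a
# minute scan and bisection on the -6 degree crossing.
oracle_sun_altitude <- function(time, lat, lon) {
  d2r <- pi / 180
  n <- as.numeric(time) / 86400 + 2440587.5 - 2451545.0
  L <- (280.460 + 0.9856474 * n) %% 360
  g <- (357.528 + 0.9856003 * n) %% 360
  lam <- L + 1.915 * sin(g * d2r) + 0.020 * sin(2 * g * d2r)
  eps <- 23.439 - 0.0000004 * n
  delta <- asin(sin(eps * d2r) * sin(lam * d2r))
  ra <- atan2(cos(eps * d2r) * sin(lam * d2r), cos(lam * d2r))
  gmst_h <- (18.697374558 + 24.06570982441908 * n) %% 24
  H <- (gmst_h * 15 + lon) * d2r - ra # local hour angle
  asin(sin(lat * d2r) * sin(delta) + cos(lat * d2r) * cos(delta) * cos(H)) / d2r
}

oracle_dawn_dusk <- function(date, lat, lon, alt = -6) {
  day0 <- as.POSIXct(paste(date, "00:00:00"), tz = "UTC")
  mins <- day0 + seq(0, 24 * 60 - 1) * 60
  a <- oracle_sun_altitude(mins, lat, lon)
  crossings <- which(diff(sign(a - alt)) != 0)
  refine <- function(i) {
    lo <- mins[i]
    hi <- mins[i + 1]
    for (k in 1:25) {
      mid <- lo + (as.numeric(hi) - as.numeric(lo)) / 2
      if (sign(oracle_sun_altitude(mid, lat, lon) - alt) ==
        sign(oracle_sun_altitude(lo, lat, lon) - alt)) lo <- mid else hi <- mid
    }
    lo + (as.numeric(hi) - as.numeric(lo)) / 2
  }
  ts <- lapply(crossings, refine)
  rising <- vapply(crossings, function(i) a[i + 1] > a[i], TRUE)
  list(
    dawn = if (any(rising)) ts[[which(rising)[1]]] else NA,
    dusk = if (any(!rising)) ts[[which(!rising)[1]]] else NA
  )
}

## ---- likelihood oracles ----

# occupancy marginal likelihood by joint enumeration over z in {0,1}^S
oracle_occupancy_loglik <- function(y, psi, p) {
  S <- nrow(y)
  J <- ncol(y)
  if (is.null(dim(p))) p <- matrix(p, S, J)
  total <- 0
  for (code in 0:(2^S - 1)) {
    z <- as.integer(intToBits(code))[seq_len(S)]
    prob <- 1
    for (i in seq_len(S)) {
      prob <- prob * ifelse(z[i] == 1, psi[i], 1 - psi[i])
      for (j in seq_len(J)) {
        if (is.na(y[i, j])) next
        pr <- z[i] * p[i, j]
        prob <- prob * ifelse(y[i, j] == 1, pr, 1 - pr)
      }
    }
    total <- total + prob
  }
  log(total)
}

# Poisson-multinomial likelihood by explicit marginalization over N <= nmax
oracle_ds_loglik <- function(counts, breaks, lambda, sigma, nmax = 500) {
  bp <- opuntiacam::bin_detection_probs(breaks, sigma)
  pi_c <- bp$cell_probs
  p0 <- bp$undetected
  ydet <- sum(counts)
  if (lambda == 0) {
    return(if (ydet == 0) 0 else -Inf)
  }
  terms <- vapply(ydet:nmax, function(N) {
    # multinomial over (counts..., N - ydet undetected)
    lmn <- lgamma(N + 1) - sum(lgamma(counts + 1)) - lgamma(N - ydet + 1) +
      sum(counts * log(pi_c)) + (N - ydet) * log(p0)
    dpois(N, lambda, log = TRUE) + lmn
  }, 0)
  m <- max(terms)
  m + log(sum(exp(terms - m)))
}

## ---- small fixtures ----

tiny_study <- function(seed = 42, n_squares = 6, days = 15,
                       species = "impala", params = true_parameters()) {
  simulate_study(
    params = params, species = species, seed = seed,
    n_squares_s1 = n_squares, n_squares_s2 = 0, days = days
  )
}

# a minimal habitat_fit-shaped object with known draws, for effect summaries
fake_fit <- function(draws_list, scaling_mean = 50, scaling_sd = 20,
                     response = "occupancy", seasons = 1) {
  P <- length(draws_list)
  n <- length(draws_list[[1]])
  arr <- array(NA_real_, c(1, n, P), dimnames = list(NULL, NULL, names(draws_list)))
  for (k in seq_len(P)) arr[1, , k] <- draws_list[[k]]
  pd <- structure(
    list(
      draws = arr, warmup = 0, iters = n, seed = 0,
      acceptance = matrix(1), par_names = names(draws_list)
    ),
    class = "posterior_draws"
  )
  structure(
    list(
      spec = model_spec(response = response, gp = FALSE),
      draws = pd,
      data = list(X = cbind(opuntia = seq(-2, 2, length.out = 5))),
      scaling = tibble::tibble(variable = "opuntia", mean = scaling_mean, sd = scaling_sd),
      seasons = seasons, site_ids = paste0("s", 1:5)
    ),
    class = "habitat_fit"
  )
}
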