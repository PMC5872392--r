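# Independent brute-force oracles. These deliberately avoid the package's
# sparse code paths: dense matrices, explicit loops, set operations.

# cosine similarity by set intersection, double loop
oracle_cosine <- function(tab) {
  sets <- split(tab$pairs$attribute, tab$pairs$entity)
  ids <- sort(tab$entities)
  S <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  for (x in ids) for (y in ids) {
    ax <- sets[[x]]
    ay <- sets[[y]]
    if (length(ax) && length(ay)) {
      S[x, y] <- length(intersect(ax, ay)) / (sqrt(length(ax)) * sqrt(length(ay)))
    }
  }
  S
}

# dense column-stochastic transition built node by node from H, G, R
oracle_transition <- function(H, G, R, phi) {
  m <- nrow(H); n <- nrow(G)
  M <- matrix(0, m + n, m + n)
  for (i in seq_len(m)) {           # walker at herb i
    hw <- H[, i]; rt <- R[i, ]
    if (sum(hw) > 0 && sum(rt) > 0) {
      M[seq_len(m), i] <- (1 - phi) * hw / sum(hw)
      M[m + seq_len(n), i] <- phi * rt / sum(rt)
    } else if (sum(hw) > 0) {
      M[seq_len(m), i] <- hw / sum(hw)
    } else if (sum(rt) > 0) {
      M[m + seq_len(n), i] <- rt / sum(rt)
    }
  }
  for (j in seq_len(n)) {           # walker at protein j
    gw <- G[, j]; rh <- R[, j]
    if (sum(gw) > 0 && sum(rh) > 0) {
      M[m + seq_len(n), m + j] <- (1 - phi) * gw / sum(gw)
      M[seq_len(m), m + j] <- phi * rh / sum(rh)
    } else if (sum(gw) > 0) {
      M[m + seq_len(n), m + j] <- gw / sum(gw)
    } else if (sum(rh) > 0) {
      M[seq_len(m), m + j] <- rh / sum(rh)
    }
  }
  M
}

# closed-form stationary distribution: p* = theta (I - (1-theta) Meff)^-1 p0,
# with dangling columns redirected to the restart vector
oracle_stationary <- function(M, p0, theta) {
  M <- as.matrix(M)
  dangling <- colSums(M) < 1e-12
  Meff <- M + outer(p0, as.numeric(dangling))
  as.numeric(theta * solve(diag(length(p0)) - (1 - theta) * Meff, p0))
}

# random association table fixture
random_table <- function(n_entities, n_attributes, p = 0.3, seed = 1) {
  set.seed(seed)
  ent <- sprintf("e%02d", seq_len(n_entities))
  att <- sprintf("a%02d", seq_len(n_attributes))
  links <- which(matrix(runif(n_entities * n_attributes) < p,
                        n_entities, n_attributes), arr.ind = TRUE)
  # guarantee every entity annotated
  extra <- setdiff(seq_len(n_entities), unique(links[, 1]))
  if (length(extra)) {
    links <- rbind(links, cbind(extra, sample(n_attributes, length(extra),
                                              replace = TRUE)))
  }
  association_table(ent[links[, 1]], att[links[, 2]])
}

# small random heterogeneous network with disjoint id namespaces
random_hetero <- function(m = 6, n = 8, seed = 1) {
  he <- random_table(m, 4, p = 0.5, seed = seed)
  pp <- random_table(n, 5, p = 0.4, seed = seed + 100)
  he$entities <- sub("^e", "h", he$entities)
  he$pairs$entity <- sub("^e", "h", he$pairs$entity)
  pp$entities <- sub("^e", "p", pp$entities)
  pp$pairs$entity <- sub("^e", "p", pp$pairs$entity)
  set.seed(seed + 200)
  links <- which(matrix(runif(m * n) < 0.3, m, n), arr.ind = TRUE)
  if (nrow(links) == 0) links <- cbind(1, 1)
  ht <- association_table(he$entities[links[, 1]], pp$entities[links[, 2]])
  net <- build_hetero_network(build_layer_network(cosine_similarity(he)),
                              build_layer_network(cosine_similarity(pp)),
                              ht)
  list(net = net, he = he, pp = pp, ht = ht)
}

# locate the real supplementary tables, if the user has provided them
real_data_path <- function(file) {
  dir <- getOption("henetrw.data_dir", "data-raw")
  file.path(dir, file)
}

load_real_table <- function(file) {
  path <- real_data_path(file)
  if (!file.exists(path)) {
    stop("supplementary data table not available at '", path,
         "'; place the converted two-column TSV there ",
         "(see README, option henetrw.data_dir)", call. = FALSE)
  }
  read_association_table(path)
}
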