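# Small fixtures built in code.

# minimal 3-attribute schema: one of each category, one binary
tiny_schema <- function() {
  attribute_schema(
    name = c("prior_bcg", "missense_snv_count", "blood_clonality"),
    category = c("clinical", "tumor", "circulating"),
    kind = c("binary", "continuous", "continuous")
  )
}

# deterministic small cohort over the tiny schema
tiny_cohort <- function(n = 6, counts = NULL, seed = 1) {
  set.seed(seed)
  d <- data.frame(
    patient_id = sprintf("pt%02d", seq_len(n)),
    prior_bcg = rep_len(c(0, 1), n),
    missense_snv_count = round(exp(rnorm(n, log(100), 0.5))),
    blood_clonality = round(runif(n, 0.05, 0.4), 3),
    expanded_clone_count = if (is.null(counts)) seq_len(n) * 3L
                           else counts,
    stringsAsFactors = FALSE
  )
  cohort_table(d, tiny_schema())
}

# random schema with at least one attribute per requested category
random_schema <- function(seed) {
  set.seed(seed)
  n_attr <- sample(3:12, 1)
  cats <- sample(c("clinical", "tumor", "circulating"), n_attr,
                 replace = TRUE)
  kinds <- sample(c("binary", "continuous"), n_attr, replace = TRUE,
                  prob = c(0.3, 0.7))
  attribute_schema(name = sprintf("attr%02d", seq_len(n_attr)),
                   category = cats, kind = kinds)
}

# random cohort over an arbitrary schema
random_cohort <- function(schema, n = 8, seed = 1, missing_rate = 0) {
  set.seed(seed)
  d <- data.frame(patient_id = sprintf("p%03d", seq_len(n)),
                  stringsAsFactors = FALSE)
  for (j in seq_len(nrow(schema))) {
    v <- if (schema$kind[j] == "binary") rbinom(n, 1, 0.5)
         else round(exp(rnorm(n, 1, 0.8)), 4)
    if (missing_rate > 0 && schema$allow_missing[j]) {
      v[runif(n) < missing_rate] <- NA
    }
    d[[schema$name[j]]] <- v
  }
  d$expanded_clone_count <- rpois(n, 20)
  cohort_table(d, schema)
}

# standardized toy design (population sd), for solver tests
toy_design <- function(n, p, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  scale(X) * sqrt(n / (n - 1))
}

# fast elastic-net config for pipeline tests where the full grid is not
# the point
fast_enet <- function() {
  elastic_net_config(l1_ratio_grid = c(0.5, 0.95), lambda_path_size = 25,
                     lambda_min_ratio = 1e-2)
}
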