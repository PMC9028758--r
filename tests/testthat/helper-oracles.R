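# Independent oracles used across test files.

# Mann-Whitney pair-count AUC: every positive-negative pair contributes 1 if
# the positive outranks the negative, 1/2 on ties.
auc_pair_oracle <- function(scores, gold) {
  pos <- ichtriage::plan_coarse(gold) == "PLAN_I"
  sp <- scores[pos]
  sn <- scores[!pos]
  total <- 0
  for (p in sp) {
    for (q in sn) {
      total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
    }
  }
  total / (length(sp) * length(sn))
}

# Naive rule evaluator: walks every rule and condition with scalar loops,
# independent of the vectorized implementation.
classify_oracle <- function(facts_row, table) {
  fired <- vapply(table$rules, function(rule) {
    all(vapply(rule$when, function(cond) {
      x <- facts_row[[cond$field]]
      if (cond$op == "unknown") return(is.na(x))
      if (cond$op == "known") return(!is.na(x))
      if (is.na(x)) return(FALSE)
      switch(cond$op,
        eq = x == cond$value, ne = x != cond$value,
        lt = x < cond$value, le = x <= cond$value,
        gt = x > cond$value, ge = x >= cond$value,
        "in" = x %in% unlist(cond$value)
      )
    }, logical(1)))
  }, logical(1))
  weights <- vapply(table$rules, function(r) r$weight, double(1))
  mandates <- vapply(table$rules, function(r) r$mandate, logical(1))
  score <- sum(weights[fired]) / table$normalizer
  mandated <- any(fired & mandates)
  plan <- if (mandated || score >= table$cut_high) {
    "PLAN_I"
  } else if (score >= table$cut_low) "PLAN_IIA" else "PLAN_IIB"
  list(plan = plan, score = score, mandated = mandated)
}

# Random (possibly partially unknown) facts for property tests.
random_facts <- function(n, na_prob = 0.2) {
  f <- ichtriage::sample_case_facts(n)
  for (col in setdiff(names(f), "record_id")) {
    mask <- stats::runif(n) < na_prob
    f[[col]][mask] <- NA
  }
  f
}

plan_rank <- function(plan) {
  # aggressiveness order: IIB < IIA < I
  match(plan, c("PLAN_IIB", "PLAN_IIA", "PLAN_I"))
}
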