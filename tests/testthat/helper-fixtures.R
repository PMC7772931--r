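# Shared fixtures, all built in code.

tiny_sets <- function() forum_sets(rdu = c("ru1", "ru2"), dar = c("da1", "da2"))

# Build a one-user timeline from a compact forum code string:
# R = RDU, D = DAR, X = unrelated forum; one post per day.
timeline_from_code <- function(code, user = "u1") {
  kinds <- strsplit(code, "")[[1]]
  forum <- vapply(kinds, function(k) switch(k, R = "ru1", D = "da1", X = "astro"), "")
  data.frame(user_id = user, forum = forum,
             timestamp = as.Date("2021-01-01") + seq_along(kinds),
             text = paste("post", seq_along(kinds)),
             stringsAsFactors = FALSE)
}

# Ten hand-built timelines with labels enumerated by inspection of the
# relapse rules (min run 5).
hand_timelines <- function() {
  codes <- c("RDDDDDR",    # 5 DAR before the RDU return -> relapsed
             "RRRDDDDDD",  # DAR run, never returns -> continued
             "DDDR",       # only 3 DAR before the return -> excluded
             "RRRR",       # never in DAR -> excluded
             "DDDDD",      # exactly the qualifying run -> continued
             "RDDDDR",     # 4 DAR before the return -> excluded
             "DRDDDDDR",   # first return after a single DAR post -> excluded
             "RDDDDDXR",   # unrelated forum does not break the run -> relapsed
             "DDDDDD",     # six DAR posts -> continued
             "RDDDDD")     # RDU only before DAR -> continued
  truth <- c("relapsed", "continued", "excluded", "excluded", "continued",
             "excluded", "excluded", "relapsed", "continued", "continued")
  list(timelines = lapply(seq_along(codes), function(i) {
         timeline_from_code(codes[i], user = paste0("u", i))
       }),
       truth = truth)
}

# Free-parameter vector for a spec from label -> value pairs.
theta_by_name <- function(spec, values) {
  labels <- spec$ptable$label[spec$ptable$free]
  miss <- setdiff(labels, names(values))
  if (length(miss)) stop("theta_by_name: missing ", paste(miss, collapse = ", "))
  unname(values[labels])
}

# True standardized estimates implied by (spec, theta).
true_standardized <- function(spec, theta) {
  f <- structure(list(spec = spec, theta_hat = theta,
                      implied_full = implied_covariance(spec, theta, full = TRUE)),
                 class = "sem_fit")
  standardize_estimates(f)
}

# Random positive-definite matrix of order p.
random_pd <- function(p) {
  A <- matrix(rnorm(p * p), p)
  crossprod(A) + diag(p) * 0.5
}
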