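# shared fixture builders (everything is generated in code at test time)

# pd matrix with exactly n5 loci depressed at P<5% of which n1 at P<1%,
# placed deterministically from the top of the canonical order
pd_with_counts <- function(pattern, n5, n1, weak = "P5", strong = "P1") {
  total <- pattern_locus_count(pattern)
  stopifnot(n1 <= n5, n5 <= total)
  cats <- rep("NS", total)
  if (n5 > 0) cats[seq_len(n5)] <- weak
  if (n1 > 0) cats[seq_len(n1)] <- strong
  pd_matrix(pattern, cats)
}

healthy_central <- function() c(20, 20, 20, 20)

healthy_record <- function(pattern = "24-2", eye = "right", md = 0) {
  field_record(eye, md, healthy_central(), pd_matrix(pattern))
}

random_pd <- function(pattern) {
  pd_matrix(pattern, sample(pd_categories(), pattern_locus_count(pattern),
                            replace = TRUE))
}

# independently coded band oracle for the pattern-deviation proportions;
# products here are at most 76 * 76, exactly representable, so plain
# integer arithmetic is arbitrary-precision at this scale
oracle_pd5 <- function(count, total) {
  if (count == 0) return("none")
  if (4 * count <= total) return("mild")        # count/total <= 1/4
  if (2 * count <= total) return("moderate")    # count/total <= 1/2
  "severe"
}

oracle_pd1 <- function(count, total) {
  if (count == 0) return("none")
  if (76 * count < 10 * total) return("mild")   # count/total < 10/76
  if (76 * count < 20 * total) return("moderate")
  "severe"
}

oracle_md <- function(md) {
  if (md >= -1) "none" else if (md >= -6) "mild" else if (md >= -12) "moderate" else "severe"
}
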