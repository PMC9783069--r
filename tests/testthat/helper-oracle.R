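# Brute-force path-enumeration oracle for life expectancy and
# reproductive value: walks every path of the empirical daily-fate tree
# explicitly (no mass-vector propagation), summing one alive-day per
# visited state for e, and discounted fecundity per visited state for v.
# Same day-counting convention as the implementation: the reference day
# counts one day.

oracle_exj <- function(tr, x, j) {
  A <- max(tr$ages)
  rec <- function(age, stage) {
    if (age >= A) return(1)
    p <- tr$trans[age + 1L, stage, ]
    nxt <- which(p > 0)
    1 + sum(vapply(nxt, function(y) p[y] * rec(age + 1L, y), numeric(1)))
  }
  rec(x, j)
}

oracle_vxj <- function(tr, sch, x, j, r) {
  A <- max(tr$ages)
  rec <- function(age, stage) {
    own <- exp(-r * (age + 1)) * sch$fxj[age + 1L, stage]
    if (age >= A) return(own)
    p <- tr$trans[age + 1L, stage, ]
    nxt <- which(p > 0)
    own + sum(vapply(nxt, function(y) p[y] * rec(age + 1L, y), numeric(1)))
  }
  exp(r * (x + 1)) * rec(x, j)
}
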