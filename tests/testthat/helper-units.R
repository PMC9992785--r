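# Minimal symbolic unit bookkeeping over base units {m, kg, s, mol, yr}.
# A qty is a value plus a named exponent vector; arithmetic propagates the
# exponents so tests can assert that a flux formula lands on
# J m^-2 yr^-1 = kg s^-2 yr^-1 without trusting the implementation.

qty <- function(value, ...) {
  u <- c(...)
  base <- c(m = 0, kg = 0, s = 0, mol = 0, yr = 0)
  base[names(u)] <- u
  structure(list(value = value, units = base), class = "qty")
}

qmul <- function(a, b) qty_new(a$value * b$value, a$units + b$units)
qdiv <- function(a, b) qty_new(a$value / b$value, a$units - b$units)
qpow <- function(a, p) qty_new(a$value^p, a$units * p)
qadd <- function(a, b) {
  stopifnot(identical(a$units, b$units))
  qty_new(a$value + b$value, a$units)
}
qty_new <- function(value, units) {
  structure(list(value = value, units = units), class = "qty")
}

expect_units <- function(q, ...) {
  want <- c(m = 0, kg = 0, s = 0, mol = 0, yr = 0)
  u <- c(...)
  want[names(u)] <- u
  expect_identical(q$units, want)
}
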