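# Minimal models built in code for unit tests.

simple_1cmt <- function(theta_cl = 5, theta_v = 10,
                        omega = c(CL = 0.09, V1 = 0.0625),
                        residual = list(type = "additive", sigma_add = 1),
                        terms_cl = list(), terms_v = list(),
                        name = "test_1cmt") {
  vanco_model(
    name = name,
    parameters = list(CL = list(theta = theta_cl, terms = terms_cl),
                      V1 = list(theta = theta_v, terms = terms_v)),
    omega = omega, residual = residual
  )
}

# one random effect on CL only
cl_only_model <- function(sigma_add = 1, omega_cl = 0.09) {
  simple_1cmt(omega = matrix(omega_cl, dimnames = list("CL", "CL")),
              residual = list(type = "additive", sigma_add = sigma_add),
              name = "test_cl_only")
}

allometric_ped_model <- function() {
  simple_1cmt(
    theta_cl = 4, theta_v = 40,
    terms_cl = list(list(kind = "power", covariate = "weight", ref = 70, exp = 0.75)),
    terms_v = list(list(kind = "power", covariate = "weight", ref = 70, exp = 1)),
    name = "test_allo"
  )
}
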