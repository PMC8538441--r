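#include <Rcpp.h>
#include "mc_core.h"

using namespace Rcpp;

// Vectorised wrappers over the sampling primitives used inside the transport
// kernel, exposed so the R-level operations exercise the exact same code.

// [[Rcpp::export]]
NumericVector mc_sample_step_cpp(NumericVector xi, double mu_tot) {
    int n = xi.size();
    NumericVector out(n);
    for (int i = 0; i < n; ++i)
        out[i] = gnrtherm::sample_step(xi[i], mu_tot);
    return out;
}

// [[Rcpp::export]]
NumericVector mc_sample_deflection_cpp(NumericVector xi, double g) {
    int n = xi.size();
    NumericVector out(n);
    for (int i = 0; i < n; ++i)
        out[i] = gnrtherm::sample_deflection(xi[i], g);
    return out;
}

// [[Rcpp::export]]
NumericVector mc_sample_azimuth_cpp(NumericVector xi) {
    int n = xi.size();
    NumericVector out(n);
    for (int i = 0; i < n; ++i)
        out[i] = gnrtherm::sample_azimuth(xi[i]);
    return out;
}

// [[Rcpp::export]]
NumericVector mc_update_direction_cpp(NumericVector dir, double cos_theta,
                                      double psi) {
    double ux = dir[0], uy = dir[1], uz = dir[2];
    gnrtherm::update_direction(ux, uy, uz, cos_theta, psi);
    return NumericVector::create(ux, uy, uz);
}
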