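#ifndef GNRTHERM_MC_CORE_H
#define GNRTHERM_MC_CORE_H

#include <cmath>

// Elementary sampling formulas of the hop-drop-spin photon cycle. These are
// the single source of truth: the transport kernel and the exported R-level
// wrappers both call them.
namespace gnrtherm {

// free path length from inverse-CDF of the exponential attenuation law
inline double sample_step(double xi, double mu_tot) {
    return -std::log(xi) / mu_tot;
}

// Henyey-Greenstein deflection cosine; isotropic branch when g == 0
inline double sample_deflection(double xi, double g) {
    if (g == 0.0) return 2.0 * xi - 1.0;
    double frac = (1.0 - g * g) / (1.0 - g + 2.0 * g * xi);
    double ct = (1.0 + g * g - frac * frac) / (2.0 * g);
    if (ct > 1.0) ct = 1.0;
    if (ct < -1.0) ct = -1.0;
    return ct;
}

inline double sample_azimuth(double xi) {
    return 2.0 * M_PI * xi;
}

// rotate a unit direction by deflection cos_theta and azimuth psi, with the
// standard pole special case when the direction is (near) parallel to z
inline void update_direction(double &ux, double &uy, double &uz,
                             double cos_theta, double psi) {
    double sin_theta = std::sqrt(std::max(0.0, 1.0 - cos_theta * cos_theta));
    double cos_psi = std::cos(psi), sin_psi = std::sin(psi);
    if (std::fabs(uz) > 0.99999) {
        double sign = (uz >= 0.0) ? 1.0 : -1.0;
        ux = sin_theta * cos_psi;
        uy = sin_theta * sin_psi;
        uz = sign * cos_theta;
    } else {
        double denom = std::sqrt(1.0 - uz * uz);
        double nx = sin_theta * (ux * uz * cos_psi - uy * sin_psi) / denom +
                    ux * cos_theta;
        double ny = sin_theta * (uy * uz * cos_psi + ux * sin_psi) / denom +
                    uy * cos_theta;
        double nz = -sin_theta * cos_psi * denom + uz * cos_theta;
        ux = nx; uy = ny; uz = nz;
    }
    // renormalise to keep |u| = 1 against accumulated round-off
    double norm = std::sqrt(ux * ux + uy * uy + uz * uz);
    ux /= norm; uy /= norm; uz /= norm;
}

} // namespace gnrtherm

#endif
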