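#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// Explicit finite-difference heat conduction on the voxel grid.
//
// The update for each voxel is
//   T' = T + dt/(rho c_v V) * ( q + sum_faces G_face (T_nb - T) )
// with face conductance G = k_harm * A / d, where k_harm = 2 k k_nb/(k + k_nb)
// is the harmonic mean of the voxel conductivities at the shared face. Face
// conductances are precomputed in R and passed in as one array per axis; a
// conductance of zero encodes an adiabatic (or inert-material) face. Voxels
// flagged `fixed` hold their temperature (Dirichlet); h_top > 0 adds a
// convective flux h A (T_amb - T) at the top face of surface voxels.

static inline void accumulate_flux(const double *T, const double *Gx,
                                   const double *Gy, const double *Gz,
                                   int nx, int ny, int nz, double *flux) {
    // x faces
    for (int k = 0; k < nz; ++k)
        for (int j = 0; j < ny; ++j)
            for (int i = 0; i + 1 < nx; ++i) {
                int a = i + nx * (j + ny * k);
                double F = Gx[i + (nx - 1) * (j + ny * k)] * (T[a + 1] - T[a]);
                flux[a] += F;
                flux[a + 1] -= F;
            }
    // y faces
    for (int k = 0; k < nz; ++k)
        for (int j = 0; j + 1 < ny; ++j)
            for (int i = 0; i < nx; ++i) {
                int a = i + nx * (j + ny * k);
                double F = Gy[i + nx * (j + (ny - 1) * k)] * (T[a + nx] - T[a]);
                flux[a] += F;
                flux[a + nx] -= F;
            }
    // z faces
    int slab = nx * ny;
    for (int k = 0; k + 1 < nz; ++k)
        for (int j = 0; j < ny; ++j)
            for (int i = 0; i < nx; ++i) {
                int a = i + nx * (j + ny * k);
                double F = Gz[a] * (T[a + slab] - T[a]);
                flux[a] += F;
                flux[a + slab] -= F;
            }
}

// [[Rcpp::export]]
NumericVector heat_step_cpp(NumericVector temp, NumericVector cap,
                            NumericVector Gx, NumericVector Gy,
                            NumericVector Gz, int nx, int ny, int nz,
                            NumericVector q, double dt, LogicalVector fixed,
                            double h_top, double T_amb, double top_area) {
    int nvox = nx * ny * nz;
    NumericVector out(nvox);
    std::vector<double> flux(nvox, 0.0);
    for (int v = 0; v < nvox; ++v) flux[v] = q[v];
    accumulate_flux(temp.begin(), Gx.begin(), Gy.begin(), Gz.begin(),
                    nx, ny, nz, flux.data());
    if (h_top > 0) {
        for (int j = 0; j < ny; ++j)
            for (int i = 0; i < nx; ++i) {
                int a = i + nx * j; // k = 0
                if (cap[a] > 0) flux[a] += h_top * top_area * (T_amb - temp[a]);
            }
    }
    for (int v = 0; v < nvox; ++v) {
        if (cap[v] > 0 && !fixed[v])
            out[v] = temp[v] + dt * flux[v] / cap[v];
        else
            out[v] = temp[v];
    }
    return out;
}

// Advance the field through a pulsed heating/cooling laser schedule and
// record snapshots. The source q is applied during heating phases only.
// Steps are clipped to phase switches and snapshot times so both are hit
// exactly; variable step sizes below the stability bound are valid for the
// explicit scheme.
// [[Rcpp::export]]
List heat_run_cpp(NumericVector temp0, NumericVector cap,
                  NumericVector Gx, NumericVector Gy, NumericVector Gz,
                  int nx, int ny, int nz,
                  NumericVector q, double tau_h, double tau_c, double tau_tot,
                  double dt_max, NumericVector snap_times,
                  IntegerVector record_idx, LogicalVector fixed,
                  double h_top, double T_amb, double top_area) {
    int nvox = nx * ny * nz;
    int n_rec = record_idx.size() > 0 ? record_idx.size() : nvox;
    int n_snap = snap_times.size();
    NumericMatrix snaps(n_rec, n_snap);
    std::vector<double> T(temp0.begin(), temp0.end());
    std::vector<double> flux(nvox);
    const double cycle = tau_h + tau_c;
    const double eps = 1e-9;

    int si = 0;
    double t = 0.0;
    // record any snapshot at t = 0
    while (si < n_snap && snap_times[si] <= eps) {
        for (int r = 0; r < n_rec; ++r)
            snaps(r, si) = record_idx.size() > 0 ? T[record_idx[r]] : T[r];
        ++si;
    }

    while (t < tau_tot - eps) {
        double in_cycle = t - cycle * std::floor(t / cycle);
        bool heating = (tau_c == 0.0) || (in_cycle < tau_h - eps);
        double t_switch = heating ? (t - in_cycle + tau_h)
                                  : (t - in_cycle + cycle);
        if (t_switch <= t + eps) t_switch = t + cycle; // fmod edge
        double t_target = tau_tot;
        if (t_switch < t_target) t_target = t_switch;
        if (si < n_snap && snap_times[si] < t_target) t_target = snap_times[si];
        double dt = t_target - t;
        if (dt > dt_max) dt = dt_max;

        for (int v = 0; v < nvox; ++v) flux[v] = heating ? q[v] : 0.0;
        accumulate_flux(T.data(), Gx.begin(), Gy.begin(), Gz.begin(),
                        nx, ny, nz, flux.data());
        if (h_top > 0) {
            for (int j = 0; j < ny; ++j)
                for (int i = 0; i < nx; ++i) {
                    int a = i + nx * j;
                    if (cap[a] > 0) flux[a] += h_top * top_area * (T_amb - T[a]);
                }
        }
        for (int v = 0; v < nvox; ++v)
            if (cap[v] > 0 && !fixed[v]) T[v] += dt * flux[v] / cap[v];
        t += dt;

        while (si < n_snap && t >= snap_times[si] - eps) {
            for (int r = 0; r < n_rec; ++r)
                snaps(r, si) = record_idx.size() > 0 ? T[record_idx[r]] : T[r];
            ++si;
        }
        Rcpp::checkUserInterrupt();
    }
    // any remaining snapshot times past tau_tot get the final field
    while (si < n_snap) {
        for (int r = 0; r < n_rec; ++r)
            snaps(r, si) = record_idx.size() > 0 ? T[record_idx[r]] : T[r];
        ++si;
    }

    NumericVector T_final(T.begin(), T.end());
    return List::create(_["snapshots"] = snaps, _["T_final"] = T_final);
}
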