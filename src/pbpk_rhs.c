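/* Whole-body PBPK right-hand side for nanoparticle biodistribution.
 *
 * State layout (0-based):
 *   organ i in 0..NORG-1: y[4i] plasma, y[4i+1] endothelium,
 *                         y[4i+2] interstitium, y[4i+3] macrophages
 *   then: venous plasma, arterial plasma, blood phagocytes, lymph node,
 *         hepatocytes, excreted (bile/feces + urine), IP absorbable depot,
 *         IP sequestered depot.
 *
 * Parameter vector layout (0-based):
 *   p[0]                 NORG
 *   p[1 + b*NORG + i]    per-organ block b for organ i, blocks in order:
 *     0 Q, 1 L, 2 Vpl, 3 VE, 4 VIS, 5 VM, 6 JL, 7 PSL, 8 sigL,
 *     9 JS, 10 PSS, 11 sigS, 12 w_ip, 13 is_portal
 *   scalars from s0 = 1 + 14*NORG:
 *     Pup, KM, CLup, CLrec, KBile, sigIS, FupM, FrecM, KAbs, VH, VLN,
 *     Vven, Vart, VBP, Ltot, CO, w_lymph_ip, CLrenal, bp_on,
 *     liver_idx, lung_idx, kidney_idx   (indices 1-based)
 */

#include <R.h>
#include <math.h>

#define NPARMS (1 + 14 * 15 + 22)

static double parms[NPARMS];

void goldpbpk_initmod(void (*odeparms)(int *, double *))
{
    int n = NPARMS;
    odeparms(&n, parms);
}

static double conc(double amount, double volume)
{
    return (volume > 0.0) ? amount / volume : 0.0;
}

/* Patlak convection-diffusion flux across one pore class. */
static double patlak(double Cp, double Ci, double J, double PS, double sig)
{
    double Jeff = J * (1.0 - sig);
    if (PS <= 0.0) {
        if (Jeff == 0.0) return 0.0;
        return Jeff * Cp;
    }
    if (Jeff == 0.0) return PS * (Cp - Ci);
    double Pe = Jeff / PS;
    /* cap only the exponent: beyond Pe ~ 700 the path is purely convective */
    if (Pe > 700.0) Pe = 700.0;
    double em = expm1(-Pe);          /* e^{-Pe} - 1 */
    return Jeff * (Cp - Ci * (1.0 + em)) / (-em);
}

void goldpbpk_derivs(int *neq, double *t, double *y, double *ydot,
                     double *yout, int *ip)
{
    const int NORG = (int) parms[0];
    const double *P = parms;
    const int s0 = 1 + 14 * NORG;

    const double Pup   = P[s0 + 0];
    const double KM    = P[s0 + 1];
    const double CLup  = P[s0 + 2];
    const double CLrec = P[s0 + 3];
    const double KBile = P[s0 + 4];
    const double sigIS = P[s0 + 5];
    const double FupM  = P[s0 + 6];
    const double FrecM = P[s0 + 7];
    const double KAbs  = P[s0 + 8];
    const double VH    = P[s0 + 9];
    const double VLN   = P[s0 + 10];
    const double Vven  = P[s0 + 11];
    const double Vart  = P[s0 + 12];
    const double VBP   = P[s0 + 13];
    const double Ltot  = P[s0 + 14];
    const double CO    = P[s0 + 15];
    const double wlym  = P[s0 + 16];
    const double CLren = P[s0 + 17];
    const double bp_on = P[s0 + 18];
    const int liver  = (int) P[s0 + 19] - 1;
    const int lung   = (int) P[s0 + 20] - 1;
    const int kidney = (int) P[s0 + 21] - 1;

#define PB(b, i) P[1 + (b) * NORG + (i)]

    const int iven = 4 * NORG, iart = iven + 1, ibp = iven + 2,
              iln = iven + 3, ihep = iven + 4, iexc = iven + 5,
              idep = iven + 6, iseq = iven + 7;

    const double Cven = conc(y[iven], Vven);
    const double Cart = conc(y[iart], Vart);
    const double CLN  = conc(y[iln], VLN);
    const double Adep = y[idep];

    double ven_in = 0.0, art_in = 0.0, portal_out = 0.0, lymph_in = 0.0;
    double Qportal_out = 0.0;

    for (int i = 0; i < NORG; i++) {
        const double Q   = PB(0, i), L = PB(1, i);
        const double Vpl = PB(2, i), VE = PB(3, i);
        const double VIS = PB(4, i), VM = PB(5, i);
        const double Cpl = conc(y[4 * i], Vpl);
        const double CE  = conc(y[4 * i + 1], VE);
        const double CIS = conc(y[4 * i + 2], VIS);
        const double CM  = conc(y[4 * i + 3], VM);

        const double f2p = patlak(Cpl, CIS, PB(6, i), PB(7, i), PB(8, i))
                         + patlak(Cpl, CIS, PB(9, i), PB(10, i), PB(11, i));
        const double f_up  = CLup * VE * Cpl;
        const double f_rec = CLrec * VE * CE;
        const double pupcl = Pup * VM * KM / (KM + CM);
        const double f_exo = CLrec * VM * CM;

        double f_phag_pl = 0.0, f_phag_is, f_exo_pl = 0.0, f_exo_is;
        if (i == liver) {
            f_phag_pl = FupM * pupcl * Cpl;
            f_phag_is = (1.0 - FupM) * pupcl * CIS;
            f_exo_pl  = FrecM * f_exo;
            f_exo_is  = (1.0 - FrecM) * f_exo;
        } else {
            f_phag_is = pupcl * CIS;
            f_exo_is  = f_exo;
        }
        const double f_lym = (1.0 - sigIS) * L * CIS;

        ydot[4 * i]     = -f2p - f_up - f_phag_pl + f_exo_pl;
        ydot[4 * i + 1] = f_up - f_rec;
        ydot[4 * i + 2] = f2p + f_rec - f_phag_is + f_exo_is - f_lym
                          + KAbs * Adep * PB(12, i);
        ydot[4 * i + 3] = f_phag_pl + f_phag_is - f_exo;
        lymph_in += f_lym;

        /* circulatory connections */
        if (i == lung) {
            ydot[4 * i] += CO * Cven - (CO - L) * Cpl;
            art_in = (CO - L) * Cpl;
        } else if (PB(13, i) > 0.5) {            /* portal organ */
            ydot[4 * i] += Q * Cart - (Q - L) * Cpl;
            portal_out += (Q - L) * Cpl;
            Qportal_out += (Q - L);
        } else if (i != liver) {
            ydot[4 * i] += Q * Cart - (Q - L) * Cpl;
            ven_in += (Q - L) * Cpl;
        }
    }

    /* liver: hepatic artery + portal inflow, venous outflow */
    {
        const double Qh = PB(0, liver), Ll = PB(1, liver);
        const double Cpl_liv = conc(y[4 * liver], PB(2, liver));
        const double Qout = Qh + Qportal_out - Ll;
        ydot[4 * liver] += Qh * Cart + portal_out - Qout * Cpl_liv;
        ven_in += Qout * Cpl_liv;
    }

    /* hepatocytes and bile */
    {
        const double CIS_liv = conc(y[4 * liver + 2], PB(4, liver));
        const double f_hep_up = CLup * VH * CIS_liv;
        const double f_hep_rec = CLrec * y[ihep];
        const double f_bile = KBile * y[ihep];
        ydot[4 * liver + 2] += -f_hep_up + f_hep_rec;
        ydot[ihep] = f_hep_up - f_hep_rec - f_bile;
        ydot[iexc] = f_bile;
    }

    /* renal clearance (0 for particles > 10 nm diameter) */
    if (CLren > 0.0) {
        const double f_ren = CLren * conc(y[4 * kidney], PB(2, kidney));
        ydot[4 * kidney] -= f_ren;
        ydot[iexc] += f_ren;
    }

    /* blood phagocytes exchanging with venous + arterial plasma */
    ydot[ibp] = 0.0;
    double bp_ven = 0.0, bp_art = 0.0;
    if (bp_on > 0.5 && VBP > 0.0) {
        const double CBP = conc(y[ibp], VBP);
        const double pupbp = Pup * VBP * KM / (KM + CBP);
        const double sv = Vven / (Vven + Vart);
        const double up_v = pupbp * sv * Cven;
        const double up_a = pupbp * (1.0 - sv) * Cart;
        const double rec = CLrec * VBP * CBP;
        ydot[ibp] = up_v + up_a - rec;
        bp_ven = -up_v + sv * rec;
        bp_art = -up_a + (1.0 - sv) * rec;
    }

    ydot[iven] = ven_in - CO * Cven + Ltot * CLN + bp_ven;
    ydot[iart] = art_in - CO * Cart + bp_art;
    ydot[iln]  = lymph_in + KAbs * Adep * wlym - Ltot * CLN;
    ydot[idep] = -KAbs * Adep;
    ydot[iseq] = 0.0;

#undef PB
}
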