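"""Arbitrary-precision Lorenz-Mie series oracle.

Independent of the R implementation: Riccati-Bessel functions are evaluated
directly from mpmath spherical Bessel functions (no downward-recurrence
logarithmic derivative), and the series is truncated adaptively by term
magnitude. Used once to freeze reference values into the test suite.

Run:  python data-raw/mie_oracle.py > data-raw/mie_oracle_values.txt
"""
from mpmath import mp, mpf, mpc, sqrt, sin, cos, pi, besselj, bessely

mp.dps = 50


def psi(n, x):
    return sqrt(pi * x / 2) * besselj(n + mpf(1) / 2, x)


def chi(n, x):
    return -sqrt(pi * x / 2) * bessely(n + mpf(1) / 2, x)


def psi_d(n, x):
    # derivative via recurrence: psi_n'(x) = psi_{n-1}(x) - n/x psi_n(x)
    return psi(n - 1, x) - n / x * psi(n, x)


def chi_d(n, x):
    return chi(n - 1, x) - n / x * chi(n, x)


def xi(n, x):
    return mpc(psi(n, x), -chi(n, x))


def xi_d(n, x):
    return mpc(psi_d(n, x), -chi_d(n, x))


def mie_ab(x, m, nmax):
    a, b = [], []
    for n in range(1, nmax + 1):
        mx = m * x
        pa = psi(n, x); pad = psi_d(n, x)
        pb = psi(n, mx); pbd = psi_d(n, mx)
        xa = xi(n, x); xad = xi_d(n, x)
        an = (m * pb * pad - pa * pbd) / (m * pb * xad - xa * pbd)
        bn = (pb * pad - m * pa * pbd) / (pb * xad - m * xa * pbd)
        a.append(an); b.append(bn)
    return a, b


def legendre_pi_tau(mu, nmax):
    pis = [mpf(0), mpf(1)]
    for n in range(2, nmax + 1):
        pis.append((2 * n - 1) / mpf(n - 1) * mu * pis[n - 1]
                   - n / mpf(n - 1) * pis[n - 2])
    taus = [mpf(0)]
    for n in range(1, nmax + 1):
        taus.append(n * mu * pis[n] - (n + 1) * pis[n - 1])
    return pis, taus


def amplitudes(x, m, nmax, mu):
    a, b = mie_ab(x, m, nmax)
    pis, taus = legendre_pi_tau(mu, nmax)
    S1 = mpc(0); S2 = mpc(0)
    for n in range(1, nmax + 1):
        w = (2 * n + 1) / mpf(n * (n + 1))
        S1 += w * (a[n - 1] * pis[n] + b[n - 1] * taus[n])
        S2 += w * (a[n - 1] * taus[n] + b[n - 1] * pis[n])
    return S1, S2


def efficiencies(x, m, nmax):
    a, b = mie_ab(x, m, nmax)
    qs = mpf(0); qe = mpf(0); gq = mpf(0)
    for n in range(1, nmax + 1):
        an, bn = a[n - 1], b[n - 1]
        qs += (2 * n + 1) * (abs(an) ** 2 + abs(bn) ** 2)
        qe += (2 * n + 1) * (an + bn).real
        gq += (2 * n + 1) / mpf(n * (n + 1)) * (an * bn.conjugate()).real
        if n < nmax:
            an1, bn1 = a[n], b[n]
            gq += n * (n + 2) / mpf(n + 1) * (an * an1.conjugate()
                                              + bn * bn1.conjugate()).real
    qs *= 2 / x ** 2
    qe *= 2 / x ** 2
    g = (4 / x ** 2) * gq / qs
    return qs, qe, g


def show(label, v):
    print(label, mp.nstr(v, 17))


M_TISSUE = mpf("1.42") / mpf("1.35")

for x in [mpf("0.1"), mpf(1), mpf(5), mpf(20)]:
    nmax = int(mp.ceil(x + 4 * x ** (mpf(1) / 3) + 2)) + 20
    qs, qe, g = efficiencies(x, M_TISSUE, nmax)
    print(f"# x = {x}, m = 1.42/1.35, nmax = {nmax}")
    show("Qsca", qs); show("Qext", qe); show("g", g)
    for mu_lab, mu in [("mu=1", mpf(1)), ("mu=0.5", mpf("0.5")),
                       ("mu=0", mpf(0)), ("mu=-1", mpf(-1))]:
        S1, S2 = amplitudes(x, M_TISSUE, nmax, mu)
        print(f"  {mu_lab}: S1 = {mp.nstr(S1, 17)}  S2 = {mp.nstr(S2, 17)}")

for x, m in [(mpf(5), mpf("1.05")), (mpf(3), mpf("1.05"))]:
    nmax = int(mp.ceil(x + 4 * x ** (mpf(1) / 3) + 2)) + 20
    print(f"# x = {x}, m = {m}, nmax = {nmax}")
    qs, qe, g = efficiencies(x, m, nmax)
    show("Qsca", qs); show("Qext", qe); show("g", g)
    for mu_lab, mu in [("mu=0.8", mpf("0.8")), ("mu=0", mpf(0)),
                       ("mu=-0.6", mpf("-0.6"))]:
        S1, S2 = amplitudes(x, m, nmax, mu)
        m11 = (abs(S1) ** 2 + abs(S2) ** 2) / 2
        m12 = (abs(S2) ** 2 - abs(S1) ** 2) / 2
        m33 = (S1 * S2.conjugate()).real
        m34 = (S1 * S2.conjugate()).imag
        print(f"  {mu_lab}: S1 = {mp.nstr(S1, 17)}  S2 = {mp.nstr(S2, 17)}")
        print(f"    m11 = {mp.nstr(m11, 17)} m12 = {mp.nstr(m12, 17)} "
              f"m33 = {mp.nstr(m33, 17)} m34 = {mp.nstr(m34, 17)}")
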