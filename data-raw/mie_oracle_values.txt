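# x = 0.1, m = 1.42/1.35, nmax = 24
Qsca 3.1172904084201865e-7
Qext 3.1172904084201865e-7
g 0.0016320071683024467
  mu=1: S1 = (7.7932260210504662e-10 - 3.4259794874202421e-5j)  S2 = (7.7932260210504662e-10 - 3.4259794874202421e-5j)
  mu=0.5: S1 = (7.7932195319093048e-10 - 3.4225063972319815e-5j)  S2 = (3.8966125759405418e-10 - 1.7113617925318699e-5j)
  mu=0: S1 = (7.7932130427695792e-10 - 3.4190358020908543e-5j)  S2 = (3.746647309182593e-16 - 1.4471827136110141e-9j)
  mu=-1: S1 = (7.7932000644944355e-10 - 3.4121020913886057e-5j)  S2 = (-7.7932000644944355e-10 + 3.4121020913886057e-5j)
# x = 1.0, m = 1.42/1.35, nmax = 27
Qsca 0.0022128544239944463
Qext 0.0022128544239944463
g 0.16894842638643711
  mu=1: S1 = (0.00055321360599861157 - 0.034895019350349686j)  S2 = (0.00055321360599861157 - 0.034895019350349686j)
  mu=0.5: S1 = (0.00054820478543816298 - 0.031508500320706697j)  S2 = (0.00027630136159508301 - 0.015866772506854653j)
  mu=0: S1 = (0.00054320760032028562 - 0.028359196199975709j)  S2 = (2.9275322260404757e-6 - 0.00014291308056045994j)
  mu=-1: S1 = (0.00053324809207139237 - 0.022720702767959717j)  S2 = (-0.00053324809207139237 + 0.022720702767959717j)
# x = 5.0, m = 1.42/1.35, nmax = 34
Qsca 0.12724583850542079
Qext 0.12724583850542079
g 0.90822053488118367
  mu=1: S1 = (0.79528649065887995 - 4.3842731092567303j)  S2 = (0.79528649065887995 - 4.3842731092567303j)
  mu=0.5: S1 = (-0.018760396547064342 + 0.32188598338392747j)  S2 = (0.027856974431745989 + 0.17322514453749726j)
  mu=0: S1 = (-0.055609167652400536 + 0.096123132313588875j)  S2 = (-0.031711093480108206 + 0.013474613303280486j)
  mu=-1: S1 = (0.031213560210613272 - 0.025150831938234279j)  S2 = (-0.031213560210613272 + 0.025150831938234279j)
# x = 20.0, m = 1.42/1.35, nmax = 53
Qsca 1.7630041358391339
Qext 1.7630041358391339
g 0.98830357531748482
  mu=1: S1 = (176.30041358391339 - 182.88599618835471j)  S2 = (176.30041358391339 - 182.88599618835471j)
  mu=0.5: S1 = (0.14415971915763505 - 1.0206923277955601j)  S2 = (-0.27150989075377699 - 0.79971573470949628j)
  mu=0: S1 = (0.33532842520145899 + 0.4006134484581298j)  S2 = (0.1449093747034036 + 0.31866720160279205j)
  mu=-1: S1 = (-0.00012435099806932273 + 0.002612806733140329j)  S2 = (0.00012435099806932273 - 0.002612806733140329j)
# x = 5.0, m = 1.05, nmax = 34
Qsca 0.11821678876280353
Qext 0.11821678876280353
g 0.90825413616391509
  mu=0.8: S1 = (0.29868765231040717 - 1.1600524793635637j)  S2 = (0.30061483567682687 - 0.95904904814112176j)
    m11 = 1.2225402123448257 m12 = -0.21239585617542839 m33 = 1.2023371656453643 m34 = -0.062272876820570968
  mu=0: S1 = (-0.052302222430045761 + 0.095225853515895655j)  S2 = (-0.029166110173437172 + 0.012891572133515262j)
    m11 = 0.0064101701318377507 m12 = -0.0053933155171150482 m33 = 0.0027530633412860583 m34 = -0.0021031098618041074
  mu=-0.6: S1 = (0.067782875230049258 - 0.16621488799793915j)  S2 = (-0.034927563775277894 + 0.079391333315888481j)
    m11 = 0.019872412841785246 m12 = -0.012349494324834637 m33 = -0.015563512272576709 m34 = 0.00042410826045057022
# x = 3.0, m = 1.05, nmax = 31
Qsca 0.038110374225362919
Qext 0.038110374225362919
g 0.79145561340369768
  mu=0.8: S1 = (0.067815301640202667 - 0.62213389135670512j)  S2 = (0.06128790241048225 - 0.50700572819386731j)
    m11 = 0.32623025465722934 m12 = -0.065419239253958897 m33 = 0.31958170421025276 m34 = -0.0037465348289455929
  mu=0: S1 = (0.012810130154887324 - 0.018120799947651874j)  S2 = (0.013378411479104142 - 0.0059502720503605349j)
    m11 = 0.00035342522825275045 m12 = -0.00013903759707522321 m33 = 0.00027920288177165028 m34 = -0.00016620375860810885
  mu=-0.6: S1 = (-0.012660472794567756 + 0.084488491778751057j)  S2 = (0.013500673440433206 - 0.049114869965765744j)
    m11 = 0.0049465657247646859 m12 = -0.0023520270896653893 m33 = -0.0043205661961179744 m34 = 0.00051883406196933349
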