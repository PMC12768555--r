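spelling,gender,plural_class
Spur,F,en
Uhr,F,en
Kur,F,en
Tür,F,en
Schnur,F,e
Frau,F,en
Bahn,F,en
Wand,F,e
Hand,F,e
Wurst,F,e
Sache,F,en
Glut,F,en
Hund,M,e
Mund,M,er
Fund,M,e
Bund,M,e
Tisch,M,e
Fisch,M,e
Bach,M,e
Park,M,s
Lehrer,M,zero
Wagen,M,zero
Raum,M,e
Baum,M,e
Traum,M,e
Tag,M,e
Weg,M,e
Klotz,M,e
Kind,N,er
Rind,N,er
Bild,N,er
Land,N,er
Buch,N,er
Dach,N,er
Fach,N,er
Auto,N,s
Sofa,N,s
Fenster,N,zero
Boot,N,e
Brot,N,e
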