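23
frame=0
Fe       0.01815642      -0.02152346      -0.02157231
N        2.03164313      -0.01286347       0.03278239
N        0.02021342       1.91184185       0.01609626
N       -2.00530623       0.02300487      -0.03919195
N        0.07557610      -2.03199974       0.07878638
C        1.09526705       2.82277251       0.03214497
C        2.40092119       2.33524187       0.00448803
C       -2.80313570      -1.04824482       0.01382754
C       -2.23475652      -2.33044632       0.03396444
C       -0.98566773      -2.77475224       0.00449164
C        2.73055696       1.01414957      -0.14965450
N       -0.01393944      -0.03922295      -2.08575585
O       -0.00666607      -0.04254538       3.79421156
O        1.08142706      -0.12071038       4.50064100
H        1.48069192       3.80701774       0.02909119
H        2.93085255       3.07397525       0.06998684
H       -3.92723496      -1.51295743      -0.03636460
H       -2.99766966      -3.02576716       0.06512713
H       -1.51023649      -3.84154685       0.01679241
H        3.71614619       1.42649051       0.05192530
H        0.95288390       0.02164090      -2.39448766
H       -0.42000615       0.79209625      -2.40448018
H       -0.38598021      -0.76046084      -2.49268003
23
frame=1
Fe      -0.00450932      -0.05553944       0.13509455
N        2.03117591      -0.04303963      -0.06810581
N       -0.04767617       1.94341307       0.00686281
N       -2.02714144      -0.07296070      -0.07468125
N        0.02904982      -1.99600087      -0.07352179
C        1.13840894       2.83266022       0.00623512
C        2.32318838       2.36004827      -0.04983196
C       -2.84428881      -1.04776245      -0.00009113
C       -2.35498904      -2.35016043      -0.02141294
C       -1.02436465      -2.70757590      -0.03068358
C        2.81289607       1.06666133      -0.10123389
N        0.00442201       0.00527569      -2.16123740
O       -0.00604483      -0.02111279       3.87054173
O        0.23345179      -0.00611751       5.10508166
H        1.52550441       3.81462126      -0.02464387
H        3.05281833       3.06963337       0.00000314
H       -3.81434945      -1.49615919       0.05614448
H       -3.01700801      -3.05827169       0.07199279
H       -1.45381591      -3.82948337      -0.05485569
H        3.87481743       1.46969371      -0.00586598
H        0.93767107      -0.08305495      -2.38044917
H       -0.44822246       0.81354922      -2.46401056
H       -0.41118436      -0.85829842      -2.44314756
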