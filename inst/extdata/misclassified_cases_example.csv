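group,feature,case,value
false_negative,ALP,73,66
false_negative,ALP,116,157
false_negative,ALP,118,46
false_negative,ALP,147,70
false_negative,ALP,94,92
false_negative,Creatinine,73,1.03
false_negative,Creatinine,116,0.69
false_negative,Creatinine,118,0.64
false_negative,Creatinine,147,0.68
false_negative,Creatinine,94,0.63
false_negative,CRP,73,0.63
false_negative,CRP,116,0.18
false_negative,CRP,118,0.00
false_negative,CRP,147,2.00
false_negative,CRP,94,0.78
false_negative,Vitamin D,73,10.9
false_negative,Vitamin D,116,13.7
false_negative,Vitamin D,118,8.23
false_negative,Vitamin D,147,28.5
false_negative,Vitamin D,94,21.8
false_negative,DM,73,0
false_negative,DM,116,0
false_negative,DM,118,0
false_negative,DM,147,0
false_negative,DM,94,0
false_negative,Height,73,179
false_negative,Height,116,156
false_negative,Height,118,161
false_negative,Height,147,146
false_negative,Height,94,158
false_negative,Weight,73,81.9
false_negative,Weight,116,56.9
false_negative,Weight,118,70.4
false_negative,Weight,147,63.6
false_negative,Weight,94,92.5
false_negative,ICW,73,28.0
false_negative,ICW,116,15.4
false_negative,ICW,118,20.4
false_negative,ICW,147,15.9
false_negative,ICW,94,20.1
false_negative,Protein,73,17.63
false_negative,Protein,116,15.92
false_negative,Protein,118,15.13
false_negative,Protein,147,16.23
false_negative,Protein,94,12.43
false_negative,Obesity,73,16.2
false_negative,Obesity,116,14.9
false_negative,Obesity,118,23.5
false_negative,Obesity,147,35.6
false_negative,Obesity,94,68.5
false_negative,Glucose,73,91
false_negative,Glucose,116,99
false_negative,Glucose,118,85
false_negative,Glucose,147,107
false_negative,Glucose,94,92
false_negative,LDL,73,160
false_negative,LDL,116,167
false_negative,LDL,118,129
false_negative,LDL,147,221
false_negative,LDL,94,129
false_negative,AAST,73,17
false_negative,AAST,116,14
false_negative,AAST,118,13
false_negative,AAST,147,15
false_negative,AAST,94,18
false_positive,ALP,176,127
false_positive,ALP,211,75
false_positive,ALP,177,73
false_positive,ALP,299,92
false_positive,ALP,194,70
false_positive,ALP,316,94
false_positive,ALP,195,56
false_positive,ALP,203,87
false_positive,ALP,250,63
false_positive,Creatinine,176,1.00
false_positive,Creatinine,211,1.09
false_positive,Creatinine,177,0.87
false_positive,Creatinine,299,1.24
false_positive,Creatinine,194,1.34
false_positive,Creatinine,316,1.04
false_positive,Creatinine,195,0.64
false_positive,Creatinine,203,0.75
false_positive,Creatinine,250,0.70
false_positive,CRP,176,0.60
false_positive,CRP,211,0.50
false_positive,CRP,177,0.55
false_positive,CRP,299,0.20
false_positive,CRP,194,0.20
false_positive,CRP,316,0.00
false_positive,CRP,195,0.00
false_positive,CRP,203,0.26
false_positive,CRP,250,0.20
false_positive,Vitamin D,176,12.7
false_positive,Vitamin D,211,26.0
false_positive,Vitamin D,177,23.3
false_positive,Vitamin D,299,36.9
false_positive,Vitamin D,194,26.7
false_positive,Vitamin D,316,15.7
false_positive,Vitamin D,195,30.5
false_positive,Vitamin D,203,25.8
false_positive,Vitamin D,250,12.2
false_positive,DM,176,0
false_positive,DM,211,0
false_positive,DM,177,0
false_positive,DM,299,0
false_positive,DM,194,1
false_positive,DM,316,0
false_positive,DM,195,0
false_positive,DM,203,0
false_positive,DM,250,1
false_positive,Height,176,177
false_positive,Height,211,179
false_positive,Height,177,165
false_positive,Height,299,172
false_positive,Height,194,176
false_positive,Height,316,172
false_positive,Height,195,163
false_positive,Height,203,153
false_positive,Height,250,169
false_positive,Weight,176,78.6
false_positive,Weight,211,95.8
false_positive,Weight,177,64.0
false_positive,Weight,299,78.8
false_positive,Weight,194,116.1
false_positive,Weight,316,96.6
false_positive,Weight,195,68.5
false_positive,Weight,203,74.7
false_positive,Weight,250,71.3
false_positive,ICW,176,25.4
false_positive,ICW,211,29.0
false_positive,ICW,177,22.4
false_positive,ICW,299,23.9
false_positive,ICW,194,32.8
false_positive,ICW,316,28.2
false_positive,ICW,195,19.6
false_positive,ICW,203,17.2
false_positive,ICW,250,23.0
false_positive,Protein,176,19.20
false_positive,Protein,211,15.85
false_positive,Protein,177,15.35
false_positive,Protein,299,18.47
false_positive,Protein,194,14.13
false_positive,Protein,316,15.87
false_positive,Protein,195,14.99
false_positive,Protein,203,13.77
false_positive,Protein,250,14.98
false_positive,Obesity,176,14.1
false_positive,Obesity,211,21.95
false_positive,Obesity,177,6.8
false_positive,Obesity,299,21.0
false_positive,Obesity,194,70.5
false_positive,Obesity,316,48.4
false_positive,Obesity,195,17.1
false_positive,Obesity,203,45.0
false_positive,Obesity,250,1.9
false_positive,Glucose,176,110
false_positive,Glucose,211,92
false_positive,Glucose,177,88
false_positive,Glucose,299,101
false_positive,Glucose,194,118
false_positive,Glucose,316,122
false_positive,Glucose,195,98
false_positive,Glucose,203,108
false_positive,Glucose,250,284
false_positive,LDL,176,149
false_positive,LDL,211,127
false_positive,LDL,177,147
false_positive,LDL,299,125
false_positive,LDL,194,88
false_positive,LDL,316,153
false_positive,LDL,195,140
false_positive,LDL,203,101
false_positive,LDL,250,79
false_positive,AAST,176,26
false_positive,AAST,211,16
false_positive,AAST,177,21
false_positive,AAST,299,17
false_positive,AAST,194,17
false_positive,AAST,316,21
false_positive,AAST,195,24
false_positive,AAST,203,29
false_positive,AAST,250,17
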