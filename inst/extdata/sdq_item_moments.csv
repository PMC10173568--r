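construct,reporter,pos,item,mean,sd
conduct,parent,1,5,0.40,0.63
conduct,parent,2,7,0.42,0.57
conduct,parent,3,12,0.04,0.24
conduct,parent,4,18,0.14,0.40
conduct,parent,5,22,0.04,0.23
conduct,self,1,5,0.53,0.65
conduct,self,2,7,0.65,0.56
conduct,self,3,12,0.15,0.40
conduct,self,4,18,0.19,0.46
conduct,self,5,22,0.11,0.35
hyperactivity,parent,1,2,0.32,0.58
hyperactivity,parent,2,10,0.23,0.52
hyperactivity,parent,3,15,0.52,0.67
hyperactivity,parent,4,21,0.65,0.62
hyperactivity,parent,5,25,0.57,0.64
hyperactivity,self,1,2,0.90,0.69
hyperactivity,self,2,10,0.64,0.72
hyperactivity,self,3,15,0.93,0.72
hyperactivity,self,4,21,0.68,0.58
hyperactivity,self,5,25,0.77,0.62
emotion,parent,1,3,0.39,0.63
emotion,parent,2,8,0.55,0.68
emotion,parent,3,13,0.27,0.55
emotion,parent,4,16,0.45,0.65
emotion,parent,5,24,0.29,0.55
emotion,self,1,3,0.45,0.65
emotion,self,2,8,1.07,0.77
emotion,self,3,13,0.47,0.65
emotion,self,4,16,1.05,0.76
emotion,self,5,24,0.49,0.66
peer,parent,1,6,0.50,0.67
peer,parent,2,11,0.16,0.45
peer,parent,3,14,0.20,0.44
peer,parent,4,19,0.18,0.47
peer,parent,5,23,0.63,0.70
peer,self,1,6,0.58,0.68
peer,self,2,11,0.16,0.42
peer,self,3,14,0.51,0.58
peer,self,4,19,0.13,0.38
peer,self,5,23,0.70,0.69
prosocial,parent,1,1,1.71,0.48
prosocial,parent,2,4,1.69,0.54
prosocial,parent,3,9,1.78,0.46
prosocial,parent,4,17,1.87,0.37
prosocial,parent,5,20,1.44,0.64
prosocial,self,1,1,1.79,0.42
prosocial,self,2,4,1.49,0.59
prosocial,self,3,9,1.65,0.52
prosocial,self,4,17,1.77,0.46
prosocial,self,5,20,1.19,0.64
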