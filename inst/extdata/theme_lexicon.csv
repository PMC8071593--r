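keyword,theme
stress,emotional
anxiety,emotional
depression,emotional
self esteem,emotional
body image,emotional
body ideal,emotional
body positivity,emotional
mental,emotional
mood,emotional
emotion,emotional
pressure,emotional
loneliness,emotional
confidence,emotional
bullying,emotional
social media,online
influencer,online
celebrity,online
online,online
screen time,online
gaming,online
video game,online
internet,online
smartphone,online
streaming,online
physical activity,physical_activity
exercise,physical_activity
sport,physical_activity
sedentary,physical_activity
active transport,physical_activity
fitness,physical_activity
gym,physical_activity
walking,physical_activity
food,food_drink
drink,food_drink
eating,food_drink
diet,food_drink
snack,food_drink
sugar,food_drink
calorie,food_drink
meal,food_drink
soda,food_drink
takeaway,food_drink
appetite,food_drink
hunger,food_drink
advertis,economic_commercial
marketing,economic_commercial
company,economic_commercial
companies,economic_commercial
profit,economic_commercial
cost,economic_commercial
price,economic_commercial
industry,economic_commercial
commercial,economic_commercial
brand,economic_commercial
sponsor,economic_commercial
promotion,economic_commercial
supply,economic_commercial
demand,economic_commercial
knowledge,knowledge
education,knowledge
information,knowledge
awareness,knowledge
literacy,knowledge
family,home_life
home,home_life
parent,home_life
household,home_life
sibling,home_life
upbringing,home_life
body weight,body_weight
weight,body_weight
obesity,body_weight
obese,body_weight
bmi,body_weight
overweight,body_weight
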